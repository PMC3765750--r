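#' @name region_classify
#' @title Threshold classification of target regions
#'
#' @description
#' Target regions are partitioned on two independent axes:
#'
#' * **bisulfite conversion**: a region is *high* if the median conversion
#'   rate of its covered nonCGc sites is `>= B`, *low* if `<= b`.
#' * **coverage**: with `N` nonCGc sites of which `n` are covered, a region
#'   is *high* if `n/N >= L` and *low* if `n/N < l` (note the strict
#'   inequality: `n/N` exactly equal to `l` is *neither*).
#'
#' The boundary semantics are deliberately asymmetric (both high rules and
#' the low-conversion rule are inclusive; the low-coverage rule is strict)
#' and are preserved exactly as stated. Regions whose defining statistic is
#' undefined (`n == 0` for conversion, `N == 0` for coverage) are classed
#' `undefined` and reported separately rather than silently dropped.
NULL

#' Classification thresholds
#'
#' @param B high-conversion cutoff (default 0.99).
#' @param b low-conversion cutoff (default 0.6); must satisfy `b < B`.
#' @param L high-coverage cutoff (default 0.5).
#' @param l low-coverage cutoff (default 0.1); must satisfy `l <= L`.
#' @return List with class `thresholds`.
#' @export
thresholds <- function(B = 0.99, b = 0.6, L = 0.5, l = 0.1) {
  vals <- c(B = B, b = b, L = L, l = l)
  if (any(vals < 0 | vals > 1))
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  if (b >= B) stop("need b < B", call. = FALSE)
  if (l > L) stop("need l <= L", call. = FALSE)
  structure(list(B = B, b = b, L = L, l = l), class = "thresholds")
}

CLASS_LEVELS <- c("high", "low", "neither", "undefined")

#' Classify regions by median bisulfite conversion
#'
#' `high` if `median_bs >= B`; `low` if `median_bs <= b`; `neither`
#' otherwise; `undefined` when no covered nonCGc site exists (`n == 0`).
#'
#' @param median_bs per-region median conversion rate (NA when undefined).
#' @param n per-region count of covered nonCGc sites.
#' @param B,b cutoffs, `b < B` (defaults 0.99 and 0.6).
#' @return Factor with levels `high`, `low`, `neither`, `undefined`.
#' @export
classify_bisulfite <- function(median_bs, n, B = 0.99, b = 0.6) {
  if (b >= B) stop("need b < B", call. = FALSE)
  cls <- rep("neither", length(median_bs))
  cls[!is.na(median_bs) & median_bs >= B] <- "high"
  cls[!is.na(median_bs) & median_bs <= b] <- "low"
  cls[n == 0L | is.na(median_bs)] <- "undefined"
  factor(cls, levels = CLASS_LEVELS)
}

#' Classify regions by nonCGc coverage fraction
#'
#' `high` if `n/N >= L`; `low` if `n/N < l` (strict); `neither` otherwise;
#' `undefined` when the region holds no nonCGc site (`N == 0`).
#'
#' @param n covered nonCGc sites per region.
#' @param N total nonCGc sites per region.
#' @param L,l cutoffs, `l <= L` (defaults 0.5 and 0.1).
#' @return Factor with levels `high`, `low`, `neither`, `undefined`.
#' @export
classify_coverage <- function(n, N, L = 0.5, l = 0.1) {
  if (l > L) stop("need l <= L", call. = FALSE)
  frac <- ifelse(N > 0L, n / N, NA_real_)
  cls <- rep("neither", length(frac))
  cls[!is.na(frac) & frac >= L] <- "high"
  cls[!is.na(frac) & frac < l] <- "low"
  cls[is.na(frac)] <- "undefined"
  factor(cls, levels = CLASS_LEVELS)
}

#' Classify a set of region summaries on both axes
#'
#' @param summaries a [region_summaries()] table.
#' @param th a [thresholds()] object.
#' @return The input with factor columns `bs_class` and `cov_class`
#'   appended.
#' @export
classify_regions <- function(summaries, th = thresholds()) {
  stopifnot(inherits(th, "thresholds"))
  summaries$bs_class <- classify_bisulfite(summaries$median_bs, summaries$n,
                                           th$B, th$b)
  summaries$cov_class <- classify_coverage(summaries$n, summaries$N,
                                           th$L, th$l)
  summaries
}

#' Check whether a low-metric class is negligibly small
#'
#' A class with fewer than `min_count` regions, or fewer than
#' `min_frac` of all target regions, is flagged *negligible*: the sample is
#' probably well sequenced on that axis and a sequence-structure comparison
#' of its high vs low groups is unnecessary.
#'
#' @param class_count regions in the class (vectorised).
#' @param total_regions total target regions (>= 1).
#' @param min_count absolute cutoff (default 10).
#' @param min_frac fractional cutoff (default 0.005, i.e. 0.5%).
#' @return Logical: TRUE where the class is negligible.
#' @export
small_group_check <- function(class_count, total_regions, min_count = 10L,
                              min_frac = 0.005) {
  stopifnot(total_regions >= 1L)
  class_count < min_count | class_count < min_frac * total_regions
}
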