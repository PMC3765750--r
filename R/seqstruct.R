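#' @name seqstruct
#' @title DNA sequence-structure profiling of target regions
#'
#' @description
#' Coverage and conversion problems often track sequence structure: GC-rich
#' or repetitive regions sequence poorly, and bisulfite treatment itself
#' fragments DNA. This module profiles each region's base composition —
#' %A, %C, %G, %T, %(C+G), %CGc (plus-strand CpG cytosines), %nonCGc
#' (plus-strand non-CpG cytosines) and %low_count (softmasked, i.e.
#' repeat/low-complexity bases) — and compares the distributions of those
#' metrics between high- and low-metric region groups. It also builds
#' in-silico RRBS target regions by MspI (`C^CGG`) digestion with fragment
#' size selection.
#'
#' Conventions: base identity is case-insensitive; lowercase contributes to
#' `%low_count` only. CpG status is assessed on the plus strand, with a
#' region-final `C` classified by the first base past the region boundary
#' when the reference extends that far (otherwise counted nonCGc). `N`
#' bases count toward region length but toward no base percentage, so
#' percentages can sum below 100 in N-containing regions.
NULL

COMPOSITION_METRICS <- c("pct_A", "pct_C", "pct_G", "pct_T", "pct_GC",
                         "pct_CGc", "pct_nonCGc", "pct_low_count")

composition_one <- function(chars, next_base) {
  len <- length(chars)
  up <- toupper(chars)
  n_low <- sum(chars %in% c("a", "c", "g", "t", "n"))
  counts <- c(A = sum(up == "A"), C = sum(up == "C"),
              G = sum(up == "G"), T = sum(up == "T"))
  is_c <- up == "C"
  follower <- c(up[-1], toupper(next_base))  # base after each position
  n_cgc <- sum(is_c & follower == "G")
  pct <- 100 * counts / len
  c(pct_A = unname(pct["A"]), pct_C = unname(pct["C"]),
    pct_G = unname(pct["G"]), pct_T = unname(pct["T"]),
    pct_GC = unname(pct["C"] + pct["G"]),
    pct_CGc = 100 * n_cgc / len,
    pct_nonCGc = 100 * (counts[["C"]] - n_cgc) / len,
    pct_low_count = 100 * n_low / len)
}

#' Base-composition profile of target regions
#'
#' @param ref named character vector of reference sequences (softmasked
#'   case preserved), as returned by [read_reference()].
#' @param regions target regions within `ref` bounds (0-based half-open).
#' @return `data.frame`, one row per region: the region coordinates, the
#'   eight percentage metrics (`pct_A`, `pct_C`, `pct_G`, `pct_T`,
#'   `pct_GC`, `pct_CGc`, `pct_nonCGc`, `pct_low_count`, each of region
#'   length), and `has_N` flagging regions whose percentages may sum below
#'   100.
#' @export
region_composition <- function(ref, regions) {
  miss <- setdiff(unique(regions$chrom), names(ref))
  if (length(miss))
    stop("chromosome not in reference: ", miss[1], call. = FALSE)
  n <- nrow(regions)
  mat <- matrix(NA_real_, n, length(COMPOSITION_METRICS),
                dimnames = list(NULL, COMPOSITION_METRICS))
  has_N <- logical(n)
  for (i in seq_len(n)) {
    seq_full <- ref[[regions$chrom[i]]]
    s <- regions$start[i]; e <- regions$end[i]
    if (e > nchar(seq_full))
      stop("region ", regions$chrom[i], ":", s, "-", e,
           " exceeds sequence length ", nchar(seq_full), call. = FALSE)
    chars <- strsplit(substr(seq_full, s + 1L, e), "", fixed = TRUE)[[1]]
    next_base <- if (e < nchar(seq_full)) substr(seq_full, e + 1L, e + 1L)
                 else ""                # region-final C counts nonCGc
    mat[i, ] <- composition_one(chars, next_base)
    has_N[i] <- any(chars %in% c("N", "n"))
  }
  cbind(regions[c("chrom", "start", "end")], as.data.frame(mat),
        has_N = has_N)
}

#' Compare sequence structure between two region groups
#'
#' Profiles both groups with [region_composition()] and tabulates, per
#' metric and group, the raw values and a five-number-plus-mean summary —
#' the plot data behind high-vs-low boxplot comparisons. If either group
#' is empty the comparison is skipped with an advisory.
#'
#' @param ref reference sequences, as in [region_composition()].
#' @param high_regions,low_regions region tables for the two groups.
#' @param metrics metric subset (default all eight).
#' @return List with class `group_comparison`: `values` (long table
#'   `group`, `metric`, `value`), `summary` (per group x metric: `n`,
#'   `min`, `q25`, `median`, `mean`, `q75`, `max`), or — when a group is
#'   empty — `advisory` text with `values = NULL`.
#' @export
compare_region_groups <- function(ref, high_regions, low_regions,
                                  metrics = COMPOSITION_METRICS) {
  metrics <- match.arg(metrics, COMPOSITION_METRICS, several.ok = TRUE)
  if (!nrow(high_regions) || !nrow(low_regions)) {
    empty <- c("high", "low")[c(!nrow(high_regions), !nrow(low_regions))]
    return(structure(list(
      values = NULL, summary = NULL,
      advisory = paste0("group(s) ", paste(empty, collapse = ", "),
                        " empty: structure comparison skipped")),
      class = "group_comparison"))
  }
  long_one <- function(regions, group) {
    comp <- region_composition(ref, regions)
    do.call(rbind, lapply(metrics, function(m)
      data.frame(group = group, metric = m, value = comp[[m]],
                 stringsAsFactors = FALSE)))
  }
  values <- rbind(long_one(high_regions, "high"),
                  long_one(low_regions, "low"))
  summ <- do.call(rbind, lapply(split(values, values[c("group", "metric")]),
    function(d) {
      st <- five_stats(d$value)
      data.frame(group = d$group[1], metric = d$metric[1], n = nrow(d),
                 min = st[["min"]], q25 = st[["q25"]],
                 median = st[["median"]], mean = st[["mean"]],
                 q75 = st[["q75"]], max = st[["max"]],
                 stringsAsFactors = FALSE)
    }))
  rownames(summ) <- NULL
  structure(list(values = values, summary = summ, advisory = NULL),
            class = "group_comparison")
}

#' Render a group comparison as PNG boxplots
#'
#' @param comparison a [compare_region_groups()] result with values.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_comparison_png <- function(comparison, path) {
  stopifnot(inherits(comparison, "group_comparison"))
  if (is.null(comparison$values)) stop(comparison$advisory, call. = FALSE)
  v <- comparison$values
  metrics <- unique(v$metric)
  grDevices::png(path, width = 250 * length(metrics), height = 500)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, length(metrics)))
  for (m in metrics) {
    d <- v[v$metric == m, ]
    graphics::boxplot(value ~ group, data = d, main = m, ylab = "%",
                      col = c("tomato", "skyblue"))
  }
  invisible(path)
}

#' In-silico MspI digestion for RRBS target construction
#'
#' MspI cuts `C^CGG`; reduced-representation bisulfite sequencing (RRBS)
#' sequences the size-selected digest fragments, which are enriched for
#' CpG-dense sequence. This emulation places a cut coordinate after the
#' first `C` of every `CCGG` occurrence (case-insensitive), takes the
#' intervals between consecutive cuts as candidate fragments (terminal
#' stretches before the first and after the last cut are not fragments),
#' and keeps those with `min_len <= length <= max_len`.
#'
#' @param ref named character vector of reference sequences.
#' @param min_len,max_len inclusive fragment-length bounds (defaults 40 and
#'   220, the usual RRBS size selection).
#' @return Target-region `data.frame` (0-based half-open), sorted and
#'   non-overlapping within each chromosome; empty when a sequence has
#'   fewer than two `CCGG` sites.
#' @export
mspi_digest <- function(ref, min_len = 40L, max_len = 220L) {
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (min_len > max_len) stop("need min_len <= max_len", call. = FALSE)
  per_chrom <- lapply(names(ref), function(chr) {
    subj <- Biostrings::DNAString(toupper(ref[[chr]]))
    m <- Biostrings::matchPattern("CCGG", subj)
    if (length(m) < 2L) return(NULL)
    cuts <- Biostrings::start(m)       # 1-based match start = 0-based C^CGG cut
    start <- cuts[-length(cuts)]
    end <- cuts[-1L]
    len <- end - start
    keep <- len >= min_len & len <= max_len
    if (!any(keep)) return(NULL)
    data.frame(chrom = chr, start = start[keep], end = end[keep],
               label = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_chrom)
  if (is.null(out))
    out <- target_regions(character(), integer(), integer())
  rownames(out) <- NULL
  out
}
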