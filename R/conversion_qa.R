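#' @name conversion_qa
#' @title Bisulfite conversion-rate assessment at nonCGc sites
#'
#' @description
#' In mammalian genomes, cytosines outside a CpG context (CHG/CHH — here
#' "nonCGc" sites) are essentially never methylated, so any apparent
#' methylation there reflects incomplete bisulfite conversion. The per-site
#' conversion rate is `1 - methylation ratio`; this module summarises it
#' over all covered nonCGc sites of a chromosome, and over the nonCGc sites
#' of each user-supplied target region.
#'
#' Order statistics (min, quartiles, median, max) are computed over
#' **covered** nonCGc sites only — uncovered sites carry no conversion
#' observation — with the standard linear-interpolation quantile rule
#' (`stats::quantile` type 7), so tabulated summaries are reproducible.
NULL

is_nonCGc <- function(tbl) tbl$context != "CG"

#' Per-site bisulfite conversion rate
#'
#' Conversion is `1 - methylation ratio`: a fully converted (unmethylated,
#' successfully treated) site reads ratio 0 and conversion 1.
#'
#' @param ratio methylation ratio(s) in `[0, 1]`; `NA` (coverage 0) is an
#'   error since conversion is undefined without an observation.
#' @return Numeric conversion rate(s) in `[0, 1]`.
#' @export
conversion_rate <- function(ratio) {
  if (any(is.na(ratio)))
    stop("conversion rate undefined for uncovered sites (ratio NA)",
         call. = FALSE)
  1 - ratio
}

five_stats <- function(x) {
  if (!length(x))
    return(c(min = NA_real_, q25 = NA_real_, median = NA_real_,
             mean = NA_real_, q75 = NA_real_, max = NA_real_))
  q <- quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  c(min = q[1], q25 = q[2], median = q[3], mean = mean(x), q75 = q[4],
    max = q[5])
}

#' Chromosome-level conversion summary
#'
#' Counts nonCGc sites (`TNCGC`), those with at least 1x coverage
#' (`TNCGCwC`), their ratio as a percentage, and the distribution of
#' conversion rates over the covered nonCGc sites.
#'
#' @param tbl a [methyl_table] containing all cytosine sites of the
#'   chromosome (covered and uncovered).
#' @param chrom optional chromosome name to restrict to; defaults to the
#'   single chromosome present.
#' @return List with class `chrom_summary`: `chrom`, `TNCGC`, `TNCGCwC`,
#'   `percent` (= 100 * TNCGCwC / TNCGC), `min`, `q25`, `median`, `mean`,
#'   `q75`, `max`, and `flagged` (TRUE when no nonCGc sites exist, leaving
#'   the statistics undefined).
#' @export
chrom_summary <- function(tbl, chrom = NULL) {
  if (!is.null(chrom)) tbl <- tbl[tbl$chrom == chrom, , drop = FALSE]
  if (is.null(chrom)) {
    chrs <- unique(tbl$chrom)
    if (length(chrs) > 1L)
      stop("table spans several chromosomes; pass `chrom`", call. = FALSE)
    chrom <- if (length(chrs)) chrs else NA_character_
  }
  ncg <- tbl[is_nonCGc(tbl), , drop = FALSE]
  TNCGC <- nrow(ncg)
  covered <- ncg[ncg$coverage >= 1L, , drop = FALSE]
  TNCGCwC <- nrow(covered)
  conv <- conversion_rate(covered$ratio)
  stats <- five_stats(conv)
  structure(c(list(chrom = chrom, TNCGC = TNCGC, TNCGCwC = TNCGCwC,
                   percent = if (TNCGC) 100 * TNCGCwC / TNCGC else NA_real_),
              as.list(stats), list(flagged = TNCGC == 0L)),
            class = "chrom_summary")
}

#' Format a coverage percentage for summary tables
#'
#' Renders `100 * count / total` with three decimal places and a trailing
#' percent sign (e.g. `"1.394%"`).
#'
#' @param count,total non-negative counts, `count <= total`, `total > 0`.
#' @return Character scalar.
#' @export
format_percent <- function(count, total) {
  stopifnot(total > 0, count >= 0, count <= total)
  sprintf("%.3f%%", 100 * count / total)
}

#' Write a chromosome-level summary table
#'
#' One header line and one row:
#' `chr TNCGC TNCGCwC Percent Min 25th_percentile Median Mean
#' 75th_percentile Max`, with `Percent` formatted by [format_percent()] and
#' conversion statistics rounded to 4 decimals.
#'
#' @param summary a [chrom_summary()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_chrom_summary <- function(summary, path) {
  stopifnot(inherits(summary, "chrom_summary"))
  hdr <- c("chr", "TNCGC", "TNCGCwC", "Percent", "Min", "25th_percentile",
           "Median", "Mean", "75th_percentile", "Max")
  num <- function(x) if (is.na(x)) "NA" else sprintf("%.4g", round(x, 4))
  row <- c(summary$chrom, summary$TNCGC, summary$TNCGCwC,
           if (summary$TNCGC) format_percent(summary$TNCGCwC, summary$TNCGC)
           else "NA",
           num(summary$min), num(summary$q25), num(summary$median),
           num(summary$mean), num(summary$q75), num(summary$max))
  writeLines(c(paste(hdr, collapse = "\t"), paste(row, collapse = "\t")),
             path)
  invisible(path)
}

#' Per-region conversion summaries
#'
#' For each target region, counts the nonCGc sites inside `[start, end)`
#' (`N`), those with coverage (`n`), and the mean and median conversion
#' rate over the covered sites. Overlapping regions each receive every site
#' they contain.
#'
#' @param tbl a [methyl_table].
#' @param regions target regions (see [target_regions()]).
#' @return `data.frame`, one row per region in input order: `chrom`,
#'   `start`, `end`, `label`, `N`, `n`, `mean_bs`, `median_bs` (`NA` when
#'   `n == 0`), `coverage_frac` (= n/N, `NA` when `N == 0`), and `flagged`
#'   (TRUE when the region holds no nonCGc site or its chromosome is absent
#'   from the table).
#' @export
region_summaries <- function(tbl, regions) {
  ncg <- tbl[is_nonCGc(tbl), , drop = FALSE]
  nreg <- nrow(regions)
  out <- data.frame(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    label = if ("label" %in% names(regions)) regions$label else NA_character_,
    N = 0L, n = 0L, mean_bs = NA_real_, median_bs = NA_real_,
    coverage_frac = NA_real_, flagged = FALSE, stringsAsFactors = FALSE)
  for (chr in unique(regions$chrom)) {
    ridx <- which(regions$chrom == chr)
    sites <- ncg[ncg$chrom == chr, , drop = FALSE]
    if (!nrow(sites)) { out$flagged[ridx] <- TRUE; next }
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = regions$start[ridx] + 1L,
                       end = regions$end[ridx]),
      IRanges::IRanges(start = sites$pos + 1L, width = 1L))
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    for (k in seq_along(ridx)) {
      i <- ridx[k]
      s <- sites[sh[qh == k], , drop = FALSE]
      out$N[i] <- nrow(s)
      cov <- s[s$coverage >= 1L, , drop = FALSE]
      out$n[i] <- nrow(cov)
      if (nrow(cov)) {
        conv <- conversion_rate(cov$ratio)
        out$mean_bs[i] <- mean(conv)
        out$median_bs[i] <- median(conv)
      }
      out$coverage_frac[i] <- if (out$N[i]) out$n[i] / out$N[i] else NA_real_
      out$flagged[i] <- out$N[i] == 0L
    }
  }
  out
}

#' Histogram data for conversion rates
#'
#' Bins values in `[0, 1]` into equal-width bins (first bin closed on the
#' left, all bins closed on the right), returning plot data rather than a
#' figure so results are scriptable; [plot_histogram_png()] renders it.
#'
#' @param values conversion rates (or any values) in `[0, 1]`.
#' @param bins number of equal-width bins (default 20).
#' @return `data.frame` with `bin_start`, `bin_end`, `count`; counts sum to
#'   `length(values)`.
#' @export
conversion_histogram <- function(values, bins = 20L) {
  bins <- as.integer(bins)
  stopifnot(bins >= 1L)
  values <- values[!is.na(values)]
  if (length(values) && (min(values) < 0 || max(values) > 1))
    stop("values must lie in [0, 1]", call. = FALSE)
  breaks <- seq(0, 1, length.out = bins + 1L)
  counts <- if (length(values)) {
    tabulate(findInterval(values, breaks, rightmost.closed = TRUE,
                          left.open = TRUE) + (values == 0), nbins = bins)
  } else integer(bins)
  data.frame(bin_start = breaks[-(bins + 1L)], bin_end = breaks[-1L],
             count = counts)
}

#' Render histogram data as a PNG
#'
#' @param hist_data a [conversion_histogram()] table.
#' @param path output PNG path.
#' @param main,xlab plot annotation.
#' @return `path`, invisibly.
#' @export
plot_histogram_png <- function(hist_data, path, main = "Conversion rate",
                               xlab = "conversion rate") {
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  graphics::barplot(hist_data$count,
                    width = hist_data$bin_end - hist_data$bin_start,
                    space = 0, col = "grey", main = main, xlab = xlab,
                    ylab = "count")
  graphics::axis(1, at = seq(0, 1, by = 0.25) * nrow(hist_data) /
                   (max(hist_data$bin_end)),
                 labels = seq(0, 1, by = 0.25))
  invisible(path)
}

#' Dataset-level conversion advisory
#'
#' Splits covered nonCGc sites into a high-conversion group A (conversion
#' >= `high_cutoff`) and a low-conversion group B, and issues a verdict
#' from the fraction in B: `investigate` above `investigate_frac`,
#' `proceed` below `proceed_frac`, `caution` in between. With a small
#' low-conversion fraction, downstream analysis can be restricted to CpG
#' sites near group-A nonCGc sites.
#'
#' @param tbl a [methyl_table].
#' @param high_cutoff conversion rate separating groups A and B
#'   (default 0.99).
#' @param investigate_frac fraction of low-conversion sites above which the
#'   verdict is `investigate` (default 0.30).
#' @param proceed_frac fraction below which it is `proceed` (default 0.05).
#' @return List with class `conversion_advisory`: `frac_low_sites`,
#'   `verdict`, `group_A_count`, `group_B_count`.
#' @export
conversion_advisory <- function(tbl, high_cutoff = 0.99,
                                investigate_frac = 0.30,
                                proceed_frac = 0.05) {
  stopifnot(proceed_frac <= investigate_frac)
  covered <- tbl[is_nonCGc(tbl) & tbl$coverage >= 1L, , drop = FALSE]
  if (!nrow(covered))
    stop("no covered nonCGc sites: advisory undefined", call. = FALSE)
  conv <- conversion_rate(covered$ratio)
  a <- sum(conv >= high_cutoff); b <- sum(conv < high_cutoff)
  frac <- b / (a + b)
  verdict <- if (frac > investigate_frac) "investigate"
             else if (frac < proceed_frac) "proceed" else "caution"
  structure(list(frac_low_sites = frac, verdict = verdict,
                 group_A_count = a, group_B_count = b),
            class = "conversion_advisory")
}
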