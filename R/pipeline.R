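#' @name pipeline
#' @title Assembled QC pipeline
#'
#' @description
#' Two entry points assemble the modules into the conventional QC runs:
#'
#' * [run_partial()] starts from a per-cytosine methylation table (the
#'   common case when alignment and methylation extraction were done with
#'   the user's own tools) and performs conversion-rate QC, region
#'   classification and sequence-structure comparison.
#' * [run_full()] additionally trims a FASTQ file first; alignment and
#'   methylation extraction sit between the two stages and are performed
#'   by external aligners, whose per-site output feeds [run_partial()].
#'
#' Output files are plain TSV with headers, named
#' `<prefix>.<chrom>.<what>` — e.g. `sample.chr1.summary.table.txt`,
#' `sample.chr1.BS.tsv`, `sample.chr1.highBS.target`,
#' `sample.chr1.lowCoverage.seq`, `sample.chr1.seq.coverage.tsv` — so runs
#' are self-describing and diffable. PNG plots are written when
#' `plots = TRUE`.
NULL

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Run configuration
#'
#' @param chrom chromosome label analysed (e.g. `"chr1"`).
#' @param prefix prefix for output file names (non-empty).
#' @param out_dir output directory, created if needed.
#' @param targets target-region file path, a region `data.frame`, or `"F"`
#'   to skip all target-level analysis.
#' @param reference reference FASTA path or named character vector; needed
#'   for sequence-structure comparison, otherwise optional.
#' @param th a [thresholds()] object.
#' @param trim a [trim_config()] (used by [run_full()]).
#' @param encoding FASTQ encoding (used by [run_full()]).
#' @param coord_base coordinate base of input methylation tables.
#' @param target_format target-file convention, see [read_targets()].
#' @param compare_bisulfite,compare_coverage whether to run the
#'   high-vs-low structure comparison on each axis (defaults TRUE).
#' @param bins histogram bin count.
#' @param plots also render PNG figures.
#' @return List with class `run_config`.
#' @export
run_config <- function(chrom, prefix, out_dir = ".", targets = NULL,
                       reference = NULL, th = thresholds(),
                       trim = trim_config(), encoding = "sanger",
                       coord_base = 1, target_format = "bed0",
                       compare_bisulfite = TRUE, compare_coverage = TRUE,
                       bins = 20L, plots = FALSE) {
  if (!nzchar(prefix)) stop("prefix must be non-empty", call. = FALSE)
  structure(list(chrom = chrom, prefix = prefix, out_dir = out_dir,
                 targets = targets, reference = reference, th = th,
                 trim = trim, encoding = encoding, coord_base = coord_base,
                 target_format = target_format,
                 compare_bisulfite = isTRUE(compare_bisulfite),
                 compare_coverage = isTRUE(compare_coverage),
                 bins = as.integer(bins), plots = isTRUE(plots)),
            class = "run_config")
}

resolve_targets <- function(config) {
  t <- config$targets
  if (is.null(t) || (is.character(t) && length(t) == 1L && t == "F"))
    return(NULL)
  if (is.character(t)) read_targets(t, config$target_format) else t
}

resolve_reference <- function(config) {
  r <- config$reference
  if (is.null(r)) return(NULL)
  if (is.character(r) && length(r) == 1L && file.exists(r))
    read_reference(r) else r
}

#' Run the partial pipeline (conversion QC onward)
#'
#' Reads a per-cytosine methylation table, writes the chromosome-level
#' conversion summary and histogram data, and — when target regions are
#' supplied — the per-region summaries, the four threshold-class region
#' lists, per-class sequence-composition tables and the high-vs-low
#' structure comparisons (the latter two require a reference).
#'
#' @param input methylation-table path or a [methyl_table].
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return Invisible list: `chrom_summary`, `advisory`, `summaries`
#'   (classified region table or NULL), `comparisons`, `small_groups`,
#'   `files` (all paths written), `log`.
#' @export
run_partial <- function(input, config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    if (!quiet) message(msg)
  }
  stem <- function(what) file.path(config$out_dir,
                                   paste0(config$prefix, ".", config$chrom,
                                          ".", what))
  tbl <- if (is.character(input))
    read_methyl_table(input, coord_base = config$coord_base) else input
  tbl <- tbl[tbl$chrom == config$chrom, , drop = FALSE]
  if (!nrow(tbl))
    stop("no sites for chromosome ", config$chrom, call. = FALSE)
  say("loaded %d cytosine sites on %s", nrow(tbl), config$chrom)
  files <- character()

  cs <- chrom_summary(tbl, config$chrom)
  files["summary"] <- write_chrom_summary(cs, stem("summary.table.txt"))
  covered <- tbl[is_nonCGc(tbl) & tbl$coverage >= 1L, , drop = FALSE]
  hist_bs <- conversion_histogram(conversion_rate(covered$ratio),
                                  config$bins)
  files["bs_hist"] <- write_tsv(hist_bs, stem("BS.tsv"))
  if (config$plots)
    files["bs_png"] <- plot_histogram_png(hist_bs, stem("BS.png"))
  adv <- conversion_advisory(tbl)
  say("conversion advisory: %s (%.1f%% of covered nonCGc sites below 0.99)",
      adv$verdict, 100 * adv$frac_low_sites)

  regions <- resolve_targets(config)
  summaries <- NULL; comparisons <- list(); small <- NULL
  if (!is.null(regions)) {
    regions <- regions[regions$chrom == config$chrom, , drop = FALSE]
    say("analysing %d target regions", nrow(regions))
    summaries <- classify_regions(region_summaries(tbl, regions), config$th)
    files["target_summary"] <- write_tsv(
      summaries[c("chrom", "start", "end", "label", "N", "n", "mean_bs",
                  "median_bs", "coverage_frac", "bs_class", "cov_class")],
      stem("target.summary.table.txt"))
    mm <- rbind(cbind(stat = "mean",
                      conversion_histogram(summaries$mean_bs, config$bins)),
                cbind(stat = "median",
                      conversion_histogram(summaries$median_bs,
                                           config$bins)))
    files["mean_median"] <- write_tsv(mm, stem("mean.median.tsv"))

    total <- nrow(summaries)
    class_sets <- list(
      highBS = summaries$bs_class == "high",
      lowBS = summaries$bs_class == "low",
      highCoverage = summaries$cov_class == "high",
      lowCoverage = summaries$cov_class == "low")
    for (nm in names(class_sets)) {
      files[paste0(nm, "_target")] <- write_tsv(
        summaries[class_sets[[nm]],
                  c("chrom", "start", "end", "label", "N", "n", "mean_bs",
                    "median_bs", "coverage_frac")],
        stem(paste0(nm, ".target")))
    }
    nonc <- summaries[summaries$N == 0L, c("chrom", "start", "end", "label")]
    files["no_nonCGc"] <- write_tsv(nonc, stem("noNonCGc.target"))
    small <- data.frame(
      class = c("lowBS", "lowCoverage"),
      count = c(sum(class_sets$lowBS), sum(class_sets$lowCoverage)),
      negligible = small_group_check(
        c(sum(class_sets$lowBS), sum(class_sets$lowCoverage)), max(total, 1L)))
    for (i in seq_len(nrow(small)))
      if (small$negligible[i])
        say("%s group is negligible (%d of %d regions): likely well sequenced on this axis",
            small$class[i], small$count[i], total)

    ref <- resolve_reference(config)
    if (!is.null(ref)) {
      for (nm in names(class_sets)) {
        sel <- summaries[class_sets[[nm]], c("chrom", "start", "end")]
        comp <- if (nrow(sel)) region_composition(ref, sel) else
          cbind(sel, as.data.frame(matrix(numeric(), 0,
            length(COMPOSITION_METRICS),
            dimnames = list(NULL, COMPOSITION_METRICS))), has_N = logical())
        files[paste0(nm, "_seq")] <- write_tsv(comp, stem(paste0(nm, ".seq")))
      }
      axes <- list(
        bisulfite = list(on = config$compare_bisulfite,
                         hi = "highBS", lo = "lowBS"),
        coverage = list(on = config$compare_coverage,
                        hi = "highCoverage", lo = "lowCoverage"))
      for (ax in names(axes)) {
        a <- axes[[ax]]
        if (!a$on) next
        cmpr <- compare_region_groups(
          ref, summaries[class_sets[[a$hi]], ],
          summaries[class_sets[[a$lo]], ])
        comparisons[[ax]] <- cmpr
        if (is.null(cmpr$values)) {
          say("%s comparison: %s", ax, cmpr$advisory)
        } else {
          files[paste0("seq_", ax)] <- write_tsv(
            cmpr$summary, stem(paste0("seq.", ax, ".tsv")))
          if (config$plots)
            files[paste0("seq_", ax, "_png")] <- plot_comparison_png(
              cmpr, stem(paste0("seq.", ax, ".boxplot.png")))
        }
      }
    } else if (config$compare_bisulfite || config$compare_coverage) {
      say("no reference supplied: sequence-structure comparison skipped")
    }
  } else {
    say("no target regions: chromosome-level analysis only")
  }
  invisible(list(chrom_summary = cs, advisory = adv, summaries = summaries,
                 comparisons = comparisons, small_groups = small,
                 files = files, log = log))
}

#' Run the full pipeline (trimming, then conversion QC)
#'
#' Trims the FASTQ input according to `config$trim` and writes the
#' surviving reads. Alignment and per-site methylation extraction are
#' performed externally; when their per-site output is supplied via
#' `ratio_table`, the QC stages of [run_partial()] follow.
#'
#' @param fastq FASTQ path or a [fastq_reads] object.
#' @param config a [run_config()].
#' @param ratio_table optional methylation-table path or [methyl_table].
#' @param quiet suppress progress messages.
#' @return Invisible list: `trim` (counts + trimmed-read path), and when
#'   `ratio_table` is given, all [run_partial()] results.
#' @export
run_full <- function(fastq, config, ratio_table = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  reads <- if (is.character(fastq)) read_fastq(fastq, config$encoding)
           else fastq
  tr <- trim_reads(reads, config$trim)
  stopifnot(tr$n_kept + tr$n_dropped == tr$n_input)  # read conservation
  out_fastq <- file.path(config$out_dir,
                         paste0(config$prefix, ".trimmed.fastq"))
  write_fastq(tr$reads, out_fastq, config$encoding)
  log <- sprintf("trimming (%s): %d reads in, %d kept, %d dropped",
                 config$trim$mode, tr$n_input, tr$n_kept, tr$n_dropped)
  if (!quiet) message(log)
  res <- list(trim = list(n_input = tr$n_input, n_kept = tr$n_kept,
                          n_dropped = tr$n_dropped, path = out_fastq),
              log = log)
  if (!is.null(ratio_table)) {
    qa <- run_partial(ratio_table, config, quiet = quiet)
    res <- c(res, qa)
    res$log <- c(log, qa$log)
  }
  invisible(res)
}
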