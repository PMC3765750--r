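#' @name trimming
#' @title Read trimming
#'
#' @description
#' Illumina bisulfite libraries often show sharply degraded base quality at
#' the 3' end and runs of `N` at both read ends; untrimmed low-quality reads
#' fail to align and are lost. Two trimming modes are provided:
#'
#' * **fixed**: remove a fixed number of bases from the 5' and 3' ends.
#' * **quality**: strip terminal `N` bases, then trim the 3' end back while
#'   the base quality is below a Phred cutoff, iterated to a fixed point so
#'   the operation is idempotent.
#'
#' Reads shorter than `min_len` after trimming are dropped (and counted),
#' never an error. Adapter trimming is out of scope: dedicated tools
#' (cutadapt, fastx) do it upstream and their FASTQ output is accepted here.
NULL

#' Trimming configuration
#'
#' @param mode `"none"`, `"fixed"` or `"quality"`.
#' @param n5 bases removed at the 5' end in fixed mode (default 5).
#' @param n3 bases removed at the 3' end in fixed mode (default 10).
#' @param qual_threshold Phred cutoff for quality mode (default 20, i.e.
#'   1% base-call error).
#' @param min_len minimum surviving read length (default 1).
#' @return List with class `trim_config`.
#' @export
trim_config <- function(mode = c("none", "fixed", "quality"), n5 = 5L,
                        n3 = 10L, qual_threshold = 20L, min_len = 1L) {
  mode <- match.arg(mode)
  n5 <- as.integer(n5); n3 <- as.integer(n3)
  qual_threshold <- as.integer(qual_threshold)
  min_len <- as.integer(min_len)
  if (n5 < 0L || n3 < 0L) stop("n5 and n3 must be >= 0", call. = FALSE)
  if (qual_threshold < 0L || qual_threshold > 93L)
    stop("qual_threshold must lie in [0, 93]", call. = FALSE)
  if (min_len < 1L) stop("min_len must be >= 1", call. = FALSE)
  structure(list(mode = mode, n5 = n5, n3 = n3,
                 qual_threshold = qual_threshold, min_len = min_len),
            class = "trim_config")
}

#' Fixed-length trimming
#'
#' Removes the first `n5` and last `n3` bases (with their qualities) from
#' every read; reads left shorter than `min_len` are dropped.
#'
#' @param reads a [fastq_reads] object.
#' @param n5,n3 bases removed at the 5'/3' end (defaults 5 and 10).
#' @param min_len minimum surviving length (default 1).
#' @return List with elements `reads` (the kept, trimmed [fastq_reads]),
#'   `n_input`, `n_kept`, `n_dropped`.
#' @export
fixed_trim <- function(reads, n5 = 5L, n3 = 10L, min_len = 1L) {
  n5 <- as.integer(n5); n3 <- as.integer(n3)
  stopifnot(n5 >= 0L, n3 >= 0L, min_len >= 1L)
  len <- nchar(reads$seq)
  keep <- len - n5 - n3 >= min_len
  kept <- subset_reads(reads, keep)
  if (length(kept)) {
    l <- nchar(kept$seq)
    kept$seq <- substr(kept$seq, n5 + 1L, l - n3)
    kept$qual <- lapply(kept$qual, function(q) {
      q[seq.int(n5 + 1L, length(q) - n3)]
    })
  }
  list(reads = kept, n_input = length(reads), n_kept = length(kept),
       n_dropped = length(reads) - length(kept))
}

# One read's quality trim, iterated to a fixed point:
#  (a) strip leading/trailing N;  (b) trim 3' bases while quality < cutoff.
# Returns the surviving index range, or NULL if the read is exhausted.
quality_trim_range <- function(bases, quals, qual_threshold) {
  lo <- 1L; hi <- length(bases)
  repeat {
    lo0 <- lo; hi0 <- hi
    while (lo <= hi && bases[lo] == "N") lo <- lo + 1L
    while (hi >= lo && bases[hi] == "N") hi <- hi - 1L
    while (hi >= lo && quals[hi] < qual_threshold) hi <- hi - 1L
    if (lo == lo0 && hi == hi0) break
  }
  if (lo > hi) NULL else c(lo, hi)
}

#' Quality-based trimming
#'
#' Strips terminal `N` bases, then trims the 3' end while the base quality
#' is below `qual_threshold`, repeating both passes until nothing changes
#' (so trimming an already-trimmed read is a no-op). Reads shorter than
#' `min_len` afterwards are dropped.
#'
#' @inheritParams fixed_trim
#' @param qual_threshold Phred cutoff (default 20).
#' @return As [fixed_trim()].
#' @export
quality_trim <- function(reads, qual_threshold = 20L, min_len = 1L) {
  qual_threshold <- as.integer(qual_threshold)
  stopifnot(qual_threshold >= 0L, min_len >= 1L)
  n <- length(reads)
  seq_out <- character(n); qual_out <- vector("list", n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    bases <- strsplit(reads$seq[i], "", fixed = TRUE)[[1]]
    rng <- quality_trim_range(bases, reads$qual[[i]], qual_threshold)
    if (!is.null(rng) && rng[2] - rng[1] + 1L >= min_len) {
      keep[i] <- TRUE
      seq_out[i] <- substr(reads$seq[i], rng[1], rng[2])
      qual_out[[i]] <- reads$qual[[i]][rng[1]:rng[2]]
    }
  }
  kept <- fastq_reads(reads$id[keep], seq_out[keep], qual_out[keep])
  list(reads = kept, n_input = n, n_kept = sum(keep),
       n_dropped = n - sum(keep))
}

#' Trim reads according to a configuration
#'
#' Dispatches to [fixed_trim()] or [quality_trim()]; `mode = "none"` passes
#' reads through. The returned counts always satisfy
#' `n_kept + n_dropped == n_input`.
#'
#' @param reads a [fastq_reads] object.
#' @param config a [trim_config].
#' @return As [fixed_trim()].
#' @export
trim_reads <- function(reads, config = trim_config()) {
  stopifnot(inherits(config, "trim_config"))
  switch(config$mode,
    none = list(reads = reads, n_input = length(reads),
                n_kept = length(reads), n_dropped = 0L),
    fixed = fixed_trim(reads, config$n5, config$n3, config$min_len),
    quality = quality_trim(reads, config$qual_threshold, config$min_len)
  )
}
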