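# Shared fixture builders. Everything is generated in code under fixed
# seeds; no stored data files.

# iid random DNA with optional N's and random softmask case
rand_seq <- function(len, p = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                     p_n = 0, p_lower = 0) {
  chars <- sample(names(p), len, replace = TRUE, prob = p)
  if (p_n > 0) chars[runif(len) < p_n] <- "N"
  if (p_lower > 0) {
    low <- runif(len) < p_lower
    chars[low] <- tolower(chars[low])
  }
  paste(chars, collapse = "")
}

rand_reads <- function(n, len = 30L, p_n = 0.02) {
  fastq_reads(
    sprintf("r%03d", seq_len(n)),
    vapply(seq_len(n), function(i)
      rand_seq(len, p_n = p_n), ""),
    lapply(seq_len(n), function(i) sample(0:40, len, replace = TRUE)))
}

# a small hand-enumerable methylation table: chrS 6 sites
hand_methyl_tbl <- function() {
  methyl_table(
    chrom = rep("chrT", 6),
    pos = c(10L, 20L, 30L, 40L, 50L, 60L),
    strand = c("+", "+", "-", "+", "-", "+"),
    context = c("CG", "CHH", "CHG", "CHH", "CHH", "CG"),
    coverage = c(5L, 4L, 0L, 10L, 2L, 0L),
    ratio = c(0.8, 0.0, NA, 0.5, 0.0, NA))
}

rand_methyl_tbl <- function(n_sites, chrom = "chrR", max_pos = 100000L,
                            p_covered = 0.6) {
  pos <- sort(sample.int(max_pos, n_sites)) - 1L
  context <- sample(c("CG", "CHG", "CHH"), n_sites, replace = TRUE,
                    prob = c(0.2, 0.3, 0.5))
  coverage <- ifelse(runif(n_sites) < p_covered,
                     1L + stats::rpois(n_sites, 4), 0L)
  ratio <- ifelse(coverage > 0,
                  round(runif(n_sites), 3), NA_real_)
  methyl_table(chrom, pos, sample(c("+", "-"), n_sites, TRUE), context,
               coverage, ratio)
}

# independent per-site brute-force region summary (the oracle used against
# region_summaries)
brute_region_summary <- function(tbl, chrom, start, end) {
  s <- tbl[tbl$chrom == chrom & tbl$context != "CG" &
             tbl$pos >= start & tbl$pos < end, , drop = FALSE]
  covered <- s[s$coverage >= 1, , drop = FALSE]
  conv <- 1 - covered$ratio
  list(N = nrow(s), n = nrow(covered),
       mean_bs = if (nrow(covered)) mean(conv) else NA_real_,
       median_bs = if (nrow(covered)) stats::median(conv) else NA_real_)
}
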