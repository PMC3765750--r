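#' @name synth_fixtures
#' @title Synthetic fixtures with known ground truth
#'
#' @description
#' Generates softmasked references, per-cytosine methylation tables, FASTQ
#' reads and target sets from a single seeded [simulation_spec()], so every
#' pipeline stage can be validated against known truth without external
#' data. The model is deliberately minimal but captures what the QC stages
#' measure:
#'
#' * the reference is a first-order base chain whose `C -> G` transition is
#'   scaled by `cpg_enrichment` while preserving the marginal GC fraction
#'   (mammalian genomes are CpG-depleted, enrichment < 1);
#' * softmasking is per-base Bernoulli with probability `repeat_fraction`;
#' * every cytosine on either strand becomes a site whose context (CG, CHG,
#'   CHH) follows from the sequence; a site is covered with probability
#'   `covered_site_fraction`, covered sites draw zero-truncated
#'   Poisson(`mean_coverage`) depth, and the methylated-read count is
#'   binomial with success probability `1 - true_conversion` at nonCGc
#'   sites and `cpg_methylation` at CG sites;
#' * simulated reads lose quality toward the 3' end at `quality_decay`
#'   Phred units per base.
NULL

#' Simulation parameters
#'
#' Defaults emulate a modest mammalian bisulfite experiment: GC fraction
#' 0.41 and CpG observed/expected 0.25 (human-like), ~45% softmasked
#' repeat content, a nearly complete bisulfite treatment (conversion
#' 0.996), typical CpG-island-shore methylation 0.75, and sparse coverage
#' (30% of sites seen, mean depth 5 where seen).
#'
#' @param seed integer seed; all randomness flows from it.
#' @param genome_length bases per simulated chromosome.
#' @param gc_fraction marginal G+C fraction in `[0, 1]`.
#' @param cpg_enrichment multiplier on the `C -> G` transition relative to
#'   independence (1 = no CpG structure; mammalian ~0.2-0.3).
#' @param repeat_fraction expected softmasked (lowercase) fraction.
#' @param true_conversion bisulfite conversion rate at nonCGc sites.
#' @param cpg_methylation methylation level at CG sites.
#' @param mean_coverage rate of the zero-truncated Poisson depth at
#'   covered sites.
#' @param covered_site_fraction probability that a site has any coverage.
#' @param n_chrom number of chromosomes (named `chrS1`, `chrS2`, ...).
#' @return List with class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L, genome_length = 100000L,
                            gc_fraction = 0.41, cpg_enrichment = 0.25,
                            repeat_fraction = 0.45, true_conversion = 0.996,
                            cpg_methylation = 0.75, mean_coverage = 5,
                            covered_site_fraction = 0.3, n_chrom = 1L) {
  fracs <- c(gc_fraction, repeat_fraction, true_conversion,
             cpg_methylation, covered_site_fraction)
  if (any(fracs < 0 | fracs > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (genome_length < 1L) stop("genome_length must be >= 1", call. = FALSE)
  if (mean_coverage < 0) stop("mean_coverage must be >= 0", call. = FALSE)
  if (cpg_enrichment < 0) stop("cpg_enrichment must be >= 0", call. = FALSE)
  pG <- gc_fraction / 2
  if (pG > 0 && cpg_enrichment * pG > 1)
    stop("cpg_enrichment forces P(G | C) above 1", call. = FALSE)
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 gc_fraction = gc_fraction, cpg_enrichment = cpg_enrichment,
                 repeat_fraction = repeat_fraction,
                 true_conversion = true_conversion,
                 cpg_methylation = cpg_methylation,
                 mean_coverage = mean_coverage,
                 covered_site_fraction = covered_site_fraction,
                 n_chrom = as.integer(n_chrom)),
            class = "simulation_spec")
}

# Transition rows of the base chain. The C row multiplies P(G) by the
# enrichment; the non-C row compensates so the marginal P(G) — and, by
# self-consistency, P(C) — stay at gc/2. Remaining mass is spread over
# A, C, T proportionally to their marginals.
base_chain <- function(gc, enrich) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  if (p[["C"]] == 0 || enrich == 1) {
    rows <- rbind(p, p)
  } else {
    gC <- enrich * p[["G"]]
    gN <- (p[["G"]] - p[["C"]] * gC) / (1 - p[["C"]])
    if (gN < 0 || gN > 1 || gC > 1)
      stop("infeasible gc_fraction / cpg_enrichment combination",
           call. = FALSE)
    other <- p[c("A", "C", "T")] / sum(p[c("A", "C", "T")])
    rowC <- c(other * (1 - gC), G = gC)[c("A", "C", "G", "T")]
    rowN <- c(other * (1 - gN), G = gN)[c("A", "C", "G", "T")]
    rows <- rbind(rowN, rowC)
  }
  dimnames(rows) <- list(c("notC", "C"), c("A", "C", "G", "T"))
  rows
}

#' Generate a softmasked reference
#'
#' @param spec a [simulation_spec()].
#' @param path optional FASTA output path (case-preserving).
#' @return Named character vector of sequences; written to `path` when
#'   given. Deterministic under the simulation seed.
#' @export
generate_reference <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    rows <- base_chain(spec$gc_fraction, spec$cpg_enrichment)
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(seq_len(spec$n_chrom), function(k) {
      L <- spec$genome_length
      u <- runif(L)
      cum <- apply(rows, 1L, cumsum)   # 4 x 2
      out <- character(L)
      prev_c <- 1L                     # first base from the non-C row
      for (i in seq_len(L)) {
        j <- min(findInterval(u[i], cum[, prev_c], left.open = TRUE) + 1L, 4L)
        out[i] <- bases[j]
        prev_c <- if (j == 2L) 2L else 1L
      }
      mask <- runif(L) < spec$repeat_fraction
      out[mask] <- tolower(out[mask])
      paste(out, collapse = "")
    }, "")
    names(seqs) <- paste0("chrS", seq_len(spec$n_chrom))
    if (!is.null(path)) write_reference(seqs, path)
    seqs
  })
}

# Cytosine sites on both strands with contexts derived from the sequence:
# plus strand looks ahead (C[G] -> CG, C[HG] -> CHG, else CHH), minus
# strand looks back on the reference ([C]G -> CG, [C H]G -> CHG, else CHH).
# Lookahead that runs off the sequence or into N defaults to CHH.
derive_sites <- function(seqchars_upper) {
  L <- length(seqchars_upper)
  at <- function(i) ifelse(i >= 1L & i <= L, seqchars_upper[pmax(pmin(i, L), 1L)],
                           NA_character_)
  plus <- which(seqchars_upper == "C")
  n1 <- at(plus + 1L); n2 <- at(plus + 2L)
  ctx_p <- ifelse(!is.na(n1) & n1 == "G", "CG",
                  ifelse(!is.na(n2) & n2 == "G", "CHG", "CHH"))
  minus <- which(seqchars_upper == "G")
  p1 <- at(minus - 1L); p2 <- at(minus - 2L)
  ctx_m <- ifelse(!is.na(p1) & p1 == "C", "CG",
                  ifelse(!is.na(p2) & p2 == "C", "CHG", "CHH"))
  data.frame(pos = c(plus, minus) - 1L,
             strand = rep(c("+", "-"), c(length(plus), length(minus))),
             context = c(ctx_p, ctx_m), stringsAsFactors = FALSE)
}

rztpois <- function(n, lambda) {
  if (lambda <= 0) return(rep(1L, n))          # degenerate floor at depth 1
  as.integer(qpois(runif(n, stats::dpois(0, lambda), 1), lambda))
}

#' Generate a per-cytosine methylation table with ground truth
#'
#' @param ref reference sequences (e.g. from [generate_reference()]).
#' @param spec a [simulation_spec()].
#' @param path optional table output path (written 1-based via
#'   [write_methyl_table()]).
#' @return A [methyl_table] sorted by chromosome and position, with
#'   attribute `truth`: a list holding the simulation parameters and the per-row true
#'   methylation probability (`true_p`).
#' @export
generate_methyl_table <- function(ref, spec, path = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed + 1L, {
    per <- lapply(names(ref), function(chr) {
      chars <- strsplit(toupper(ref[[chr]]), "", fixed = TRUE)[[1]]
      sites <- derive_sites(chars)
      sites <- sites[order(sites$pos, sites$strand), , drop = FALSE]
      sites$chrom <- chr
      sites
    })
    sites <- do.call(rbind, per)
    ns <- nrow(sites)
    true_p <- ifelse(sites$context == "CG", spec$cpg_methylation,
                     1 - spec$true_conversion)
    covered <- runif(ns) < spec$covered_site_fraction
    coverage <- integer(ns)
    coverage[covered] <- rztpois(sum(covered), spec$mean_coverage)
    meth <- integer(ns)
    meth[covered] <- rbinom(sum(covered), coverage[covered],
                            true_p[covered])
    ratio <- ifelse(coverage > 0L, meth / pmax(coverage, 1L), NA_real_)
    tbl <- methyl_table(sites$chrom, sites$pos, sites$strand,
                        sites$context, coverage, ratio)
    attr(tbl, "truth") <- list(spec = spec, true_p = true_p)
    if (!is.null(path)) write_methyl_table(tbl, path, coord_base = 1)
    tbl
  })
}

#' Generate FASTQ reads from a reference
#'
#' Reads are drawn uniformly from the reference (plus strand, uppercased),
#' with per-base Phred qualities starting near `q_start` and declining
#' toward the 3' end by `quality_decay` Phred units per base (plus noise),
#' mimicking the 3'-end quality loss typical of Illumina runs.
#'
#' @param ref reference sequences.
#' @param n_reads number of reads.
#' @param read_len read length (must fit inside every sequence).
#' @param quality_decay Phred units lost per base toward the 3' end.
#' @param encoding FASTQ encoding for `path`.
#' @param seed integer seed.
#' @param path optional FASTQ output path.
#' @param q_start 5'-end quality (default 38).
#' @return A [fastq_reads] object, deterministic under `seed`.
#' @export
generate_reads <- function(ref, n_reads, read_len = 50L, quality_decay = 0.4,
                           encoding = c("sanger", "illumina"), seed = 1L,
                           path = NULL, q_start = 38L) {
  encoding <- match.arg(encoding)
  read_len <- as.integer(read_len)
  if (any(nchar(ref) < read_len))
    stop("read_len exceeds a reference sequence length", call. = FALSE)
  with_seed(seed, {
    chrs <- sample(names(ref), n_reads, replace = TRUE,
                   prob = nchar(ref) / sum(nchar(ref)))
    starts <- vapply(chrs, function(chr)
      sample.int(nchar(ref[[chr]]) - read_len + 1L, 1L), 1L)
    seqs <- toupper(substr(ref[chrs], starts, starts + read_len - 1L))
    quals <- lapply(seq_len(n_reads), function(i) {
      q <- q_start - quality_decay * (seq_len(read_len) - 1L) +
        rnorm(read_len, sd = 2)
      pmin(pmax(as.integer(round(q)), 2L), 40L)
    })
    reads <- fastq_reads(sprintf("read_%06d", seq_len(n_reads)), seqs, quals)
    if (!is.null(path)) write_fastq(reads, path, encoding)
    reads
  })
}

#' Generate random target regions
#'
#' @param ref reference sequences.
#' @param n_regions number of regions.
#' @param length_range inclusive region-length bounds.
#' @param seed integer seed.
#' @param path optional target-file output path (BED0).
#' @return Target-region `data.frame`, reproducible under `seed`.
#' @export
generate_targets <- function(ref, n_regions, length_range = c(500L, 2000L),
                             seed = 1L, path = NULL) {
  length_range <- as.integer(length_range)
  if (length_range[1] > min(nchar(ref)))
    stop("minimum region length exceeds a reference sequence",
         call. = FALSE)
  with_seed(seed, {
    if (n_regions == 0L) {
      regions <- target_regions(character(), integer(), integer())
    } else {
      chrs <- sample(names(ref), n_regions, replace = TRUE,
                     prob = nchar(ref) / sum(nchar(ref)))
      lens <- pmin(sample(seq.int(length_range[1], length_range[2]),
                          n_regions, replace = TRUE), nchar(ref[chrs]))
      starts <- vapply(seq_len(n_regions), function(i)
        sample.int(nchar(ref[[chrs[i]]]) - lens[i] + 1L, 1L) - 1L, 1L)
      regions <- target_regions(chrs, starts, starts + lens,
                                sprintf("region_%04d", seq_len(n_regions)))
    }
    if (!is.null(path)) write_targets(regions, path)
    regions
  })
}

#' Write a complete fixture bundle
#'
#' Emits reference FASTA, methylation table, target file, FASTQ reads and
#' a JSON manifest recording the simulation parameters and ground truth
#' summary, so tests and demonstrations never re-infer the truth.
#'
#' @param spec a [simulation_spec()].
#' @param dir output directory (created if needed).
#' @param n_regions,n_reads,read_len sizes of the target and read sets.
#' @return Invisible list of the generated objects and file paths.
#' @export
write_fixture_bundle <- function(spec, dir, n_regions = 50L, n_reads = 500L,
                                 read_len = 50L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(fasta = file.path(dir, "reference.fa"),
                table = file.path(dir, "methyl_table.tsv"),
                targets = file.path(dir, "targets.bed"),
                fastq = file.path(dir, "reads.fastq"),
                manifest = file.path(dir, "manifest.json"))
  ref <- generate_reference(spec, paths$fasta)
  tbl <- generate_methyl_table(ref, spec, paths$table)
  regions <- generate_targets(ref, n_regions, seed = spec$seed + 2L,
                              path = paths$targets)
  reads <- generate_reads(ref, n_reads, read_len, seed = spec$seed + 3L,
                          path = paths$fastq)
  manifest <- list(spec = unclass(spec),
                   ground_truth = list(
                     true_conversion = spec$true_conversion,
                     cpg_methylation = spec$cpg_methylation,
                     n_sites = nrow(tbl),
                     n_covered = sum(tbl$coverage > 0L)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(ref = ref, table = tbl, regions = regions, reads = reads,
                 paths = paths))
}
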