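test_that("conversion rate is one minus the methylation ratio", {
  expect_equal(conversion_rate(0), 1)
  expect_equal(conversion_rate(1), 0)
  expect_equal(conversion_rate(0.0039), 0.9961)
  expect_error(conversion_rate(NA_real_), "undefined")
})

test_that("chromosome summary counts and order statistics are correct", {
  # 5 nonCGc sites, 2 covered with conversions {1.0, 0.5}
  tbl <- methyl_table(
    chrom = rep("chrX", 6),
    pos = 1:6, strand = "+",
    context = c("CHH", "CHG", "CHH", "CHH", "CHG", "CG"),
    coverage = c(3L, 0L, 0L, 8L, 0L, 5L),
    ratio = c(0.0, NA, NA, 0.5, NA, 0.9))
  cs <- chrom_summary(tbl, "chrX")
  expect_equal(cs$TNCGC, 5L)
  expect_equal(cs$TNCGCwC, 2L)
  expect_equal(cs$percent, 40)
  expect_equal(format_percent(cs$TNCGCwC, cs$TNCGC), "40.000%")
  expect_equal(cs$min, 0.5)
  expect_equal(cs$median, 0.75)
  expect_equal(cs$mean, 0.75)
  expect_equal(cs$max, 1.0)
  expect_false(cs$flagged)

  # all-CG table has no nonCGc sites: flagged, statistics undefined
  cg <- methyl_table("chrX", 1:3, "+", "CG", c(1L, 2L, 3L),
                     c(0.5, 0.5, 0.5))
  cs0 <- chrom_summary(cg, "chrX")
  expect_equal(cs0$TNCGC, 0L)
  expect_true(cs0$flagged)
  expect_true(is.na(cs0$mean))
})

test_that("percent is exactly 100 * TNCGCwC / TNCGC and stats are permutation-invariant", {
  withr::local_seed(21)
  for (rep in 1:5) {
    tbl <- rand_methyl_tbl(400)
    cs <- chrom_summary(tbl, "chrR")
    expect_equal(cs$percent, 100 * cs$TNCGCwC / cs$TNCGC)
    shuffled <- tbl[sample.int(nrow(tbl)), ]
    cs2 <- chrom_summary(shuffled, "chrR")
    expect_equal(cs2[c("min", "q25", "median", "mean", "q75", "max")],
                 cs[c("min", "q25", "median", "mean", "q75", "max")])
    # sort-based oracle for the order statistics
    conv <- sort(1 - tbl$ratio[tbl$context != "CG" & tbl$coverage >= 1])
    expect_equal(cs$min, conv[1])
    expect_equal(cs$max, conv[length(conv)])
    expect_equal(cs$median, stats::median(conv))
    expect_equal(cs$q25, unname(quantile(conv, 0.25, type = 7)))
  }
})

test_that("region summaries match hand computation and handle empties", {
  tbl <- methyl_table(
    "chr1", c(10L, 20L, 30L, 40L), "+",
    c("CHH", "CHG", "CHH", "CHH"),
    c(4L, 2L, 5L, 0L), c(0.0, 0.0, 0.8, NA))
  # region [5, 35) holds the three covered sites: conversions 1, 1, 0.2
  rs <- region_summaries(tbl, target_regions("chr1", 5L, 35L))
  expect_equal(rs$N, 3L)
  expect_equal(rs$n, 3L)
  expect_equal(rs$mean_bs, mean(c(1, 1, 0.2)))
  expect_equal(rs$median_bs, 1)

  # region with nonCGc sites but none covered
  rs0 <- region_summaries(tbl, target_regions("chr1", 39L, 45L))
  expect_equal(rs0$N, 1L)
  expect_equal(rs0$n, 0L)
  expect_true(is.na(rs0$mean_bs))
  expect_equal(rs0$coverage_frac, 0)

  # chromosome absent from the table: flagged with N = 0
  rs_na <- region_summaries(tbl, target_regions("chr9", 0L, 100L))
  expect_equal(rs_na$N, 0L)
  expect_true(rs_na$flagged)

  # half-open boundaries: site at pos 10 is in [10, 11) but not [0, 10)
  expect_equal(region_summaries(tbl, target_regions("chr1", 10L, 11L))$N, 1L)
  expect_equal(region_summaries(tbl, target_regions("chr1", 0L, 10L))$N, 0L)
})

test_that("region summaries agree with a per-site brute-force scan", {
  withr::local_seed(31)
  tbl <- rand_methyl_tbl(10000, max_pos = 50000L)
  start <- sample.int(49000L, 100) - 1L
  regions <- target_regions("chrR", start, start + sample.int(2000L, 100))
  rs <- region_summaries(tbl, regions)
  for (i in seq_len(nrow(regions))) {
    oracle <- brute_region_summary(tbl, "chrR", regions$start[i],
                                   regions$end[i])
    expect_equal(rs$N[i], oracle$N)
    expect_equal(rs$n[i], oracle$n)
    expect_equal(rs$mean_bs[i], oracle$mean_bs)
    expect_equal(rs$median_bs[i], oracle$median_bs)
  }
})

test_that("whole-chromosome region reproduces chromosome-level statistics", {
  withr::local_seed(5)
  tbl <- rand_methyl_tbl(3000, max_pos = 30000L)
  cs <- chrom_summary(tbl, "chrR")
  rs <- region_summaries(tbl, target_regions("chrR", 0L, 30000L))
  expect_equal(rs$N, cs$TNCGC)
  expect_equal(rs$n, cs$TNCGCwC)
  expect_equal(rs$mean_bs, cs$mean)
  expect_equal(rs$median_bs, cs$median)
})

test_that("histogram counts match an independent binning oracle", {
  expect_equal(conversion_histogram(rep(1, 50), bins = 10)$count,
               c(rep(0L, 9), 50L))
  expect_equal(sum(conversion_histogram(numeric(), bins = 10)$count), 0L)

  withr::local_seed(17)
  vals <- pmin(pmax(rbeta(10000, 20, 0.5), 0), 1)
  h <- conversion_histogram(vals, bins = 25)
  oracle <- as.integer(table(cut(vals, seq(0, 1, length.out = 26),
                                 include.lowest = TRUE, right = TRUE)))
  expect_equal(h$count, oracle)
  expect_equal(sum(h$count), length(vals))
})

test_that("advisory verdicts follow the low-conversion fraction cutoffs", {
  mk <- function(n_low, n_high) {
    n <- n_low + n_high
    methyl_table("c", seq_len(n), "+", "CHH", rep(10L, n),
                 c(rep(0.5, n_low), rep(0.0, n_high)))
  }
  expect_equal(conversion_advisory(mk(40, 60))$verdict, "investigate")
  expect_equal(conversion_advisory(mk(0, 50))$verdict, "proceed")
  expect_equal(conversion_advisory(mk(0, 50))$group_B_count, 0L)

  # 10% low-conversion sites: caution, counts match construction
  adv <- conversion_advisory(mk(100, 900))
  expect_equal(adv$verdict, "caution")
  expect_equal(adv$group_A_count, 900L)
  expect_equal(adv$group_B_count, 100L)
  expect_equal(adv$frac_low_sites, 0.1)

  empty <- methyl_table("c", 1L, "+", "CG", 5L, 0.2)
  expect_error(conversion_advisory(empty), "no covered nonCGc")
})

test_that("summary table renders the header and formatted percent cell", {
  withr::local_seed(2)
  tbl <- rand_methyl_tbl(200)
  f <- withr::local_tempfile(fileext = ".txt")
  write_chrom_summary(chrom_summary(tbl, "chrR"), f)
  lines <- readLines(f)
  expect_match(lines[1], "^chr\tTNCGC\tTNCGCwC\tPercent\tMin\t25th_percentile")
  cells <- strsplit(lines[2], "\t")[[1]]
  expect_match(cells[4], "^[0-9]+\\.[0-9]{3}%$")
})
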