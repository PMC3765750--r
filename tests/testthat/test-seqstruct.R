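test_that("composition of hand-counted sequences is exact", {
  ref <- c(chr = "ACGCGT")
  comp <- region_composition(ref, target_regions("chr", 0L, 6L))
  expect_equal(comp$pct_A, 100 / 6)
  expect_equal(comp$pct_C, 200 / 6)
  expect_equal(comp$pct_G, 200 / 6)
  expect_equal(comp$pct_T, 100 / 6)
  expect_equal(comp$pct_GC, 400 / 6)
  expect_equal(comp$pct_CGc, 200 / 6)   # both Cs precede a G
  expect_equal(comp$pct_nonCGc, 0)
  expect_equal(comp$pct_low_count, 0)

  # softmask changes only %low_count
  low <- region_composition(c(chr = "acgcgt"), target_regions("chr", 0L, 6L))
  expect_equal(low[COMPOSITION_SET <- c("pct_A", "pct_C", "pct_G", "pct_T",
                                        "pct_GC", "pct_CGc", "pct_nonCGc")],
               comp[COMPOSITION_SET])
  expect_equal(low$pct_low_count, 100)

  aaaa <- region_composition(c(chr = "AAAA"), target_regions("chr", 0L, 4L))
  expect_equal(aaaa$pct_A, 100)
  expect_equal(aaaa$pct_C + aaaa$pct_CGc + aaaa$pct_nonCGc, 0)
})

test_that("a region-final C is classified by the base past the boundary", {
  ref <- c(chr = "AACGAA")
  # region [0, 3) ends on the C at pos 2; pos 3 holds G -> CGc
  in_reach <- region_composition(ref, target_regions("chr", 0L, 3L))
  expect_equal(in_reach$pct_CGc, 100 / 3)
  expect_equal(in_reach$pct_nonCGc, 0)
  # sequence-final C with nothing beyond counts nonCGc
  end_c <- region_composition(c(chr = "AAC"), target_regions("chr", 0L, 3L))
  expect_equal(end_c$pct_CGc, 0)
  expect_equal(end_c$pct_nonCGc, 100 / 3)
})

test_that("N bases count toward length but no base percentage", {
  comp <- region_composition(c(chr = "ACGTN"), target_regions("chr", 0L, 5L))
  expect_equal(comp$pct_A + comp$pct_C + comp$pct_G + comp$pct_T, 80)
  expect_true(comp$has_N)
  expect_error(region_composition(c(chr = "ACGT"),
                                  target_regions("chr", 0L, 10L)),
               "exceeds")
})

test_that("composition identities hold on random sequences", {
  withr::local_seed(23)
  for (i in 1:1000) {
    len <- sample(10:200, 1)
    with_n <- i %% 5 == 0
    ref <- c(chr = rand_seq(len, p_n = if (with_n) 0.05 else 0,
                            p_lower = runif(1)))
    comp <- region_composition(ref, target_regions("chr", 0L, len))
    expect_equal(comp$pct_CGc + comp$pct_nonCGc, comp$pct_C)
    expect_equal(comp$pct_GC, comp$pct_C + comp$pct_G)
    if (!comp$has_N)
      expect_equal(comp$pct_A + comp$pct_C + comp$pct_G + comp$pct_T, 100)
  }
})

test_that("group comparison summarises both groups and respects symmetry", {
  withr::local_seed(29)
  ref <- c(chr = rand_seq(5000, p_lower = 0.3))
  s <- sort(sample.int(4800, 12)) - 1L
  regions <- target_regions("chr", s, s + 150L)
  same <- compare_region_groups(ref, regions, regions)
  hi <- same$summary[same$summary$group == "high", -1]
  lo <- same$summary[same$summary$group == "low", -1]
  rownames(hi) <- rownames(lo) <- NULL
  expect_equal(hi, lo)

  # single-region groups: summaries equal the region's own composition
  one <- compare_region_groups(ref, regions[1, ], regions[2, ])
  comp1 <- region_composition(ref, regions[1, ])
  su <- one$summary
  expect_equal(su$median[su$group == "high" & su$metric == "pct_GC"],
               comp1$pct_GC)
  expect_equal(su$min[su$group == "high" & su$metric == "pct_A"],
               comp1$pct_A)

  # group order within a group does not matter
  shuf <- compare_region_groups(ref, regions[sample(nrow(regions)), ],
                                regions)
  expect_equal(shuf$summary, same$summary)

  # empty group: advisory instead of comparison
  empty <- compare_region_groups(ref, regions[0, ], regions)
  expect_null(empty$values)
  expect_match(empty$advisory, "high")
})

test_that("GC-stratified groups order the pct_GC summaries accordingly", {
  withr::local_seed(37)
  gc_rich <- vapply(1:8, function(i)
    rand_seq(300, p = c(A = 0.1, C = 0.4, G = 0.4, T = 0.1)), "")
  gc_poor <- vapply(1:8, function(i)
    rand_seq(300, p = c(A = 0.4, C = 0.1, G = 0.1, T = 0.4)), "")
  ref <- setNames(c(gc_rich, gc_poor), paste0("chr", 1:16))
  rich_regions <- target_regions(paste0("chr", 1:8), 0L, 300L)
  poor_regions <- target_regions(paste0("chr", 9:16), 0L, 300L)
  cmpr <- compare_region_groups(ref, rich_regions, poor_regions)
  su <- cmpr$summary[cmpr$summary$metric == "pct_GC", ]
  expect_gt(su$median[su$group == "high"], su$median[su$group == "low"])
})

test_that("MspI digestion matches hand enumeration", {
  # CCGG at offsets 3 and 11 -> cuts at 4 and 12 -> fragment [4, 12)
  ref <- c(chr = "AAACCGGTTTTCCGGAA")
  frags <- mspi_digest(ref, min_len = 2, max_len = 50)
  expect_equal(frags$start, 4L)
  expect_equal(frags$end, 12L)
  # with the default 40-220 size selection the 8-mer is rejected
  expect_equal(nrow(mspi_digest(ref)), 0L)

  # adjacent motifs: cuts at 1 and 5 -> fragment [1, 5)
  adj <- mspi_digest(c(chr = "CCGGCCGG"), min_len = 1, max_len = 10)
  expect_equal(adj$start, 1L)
  expect_equal(adj$end, 5L)

  # fewer than two sites -> nothing
  expect_equal(nrow(mspi_digest(c(chr = "AAACCGGAAA"), 1, 100)), 0L)
  expect_equal(nrow(mspi_digest(c(chr = "ACGTACGT"), 1, 100)), 0L)

  # case-insensitive motif matching
  soft <- mspi_digest(c(chr = "AAAccggTTTTCcGgAA"), 2, 50)
  expect_equal(soft$start, 4L)
  expect_equal(soft$end, 12L)
})

test_that("digest fragments are in-bounds, sorted and non-overlapping", {
  withr::local_seed(43)
  for (i in 1:20) {
    ref <- c(chr = rand_seq(4000, p = c(A = 0.2, C = 0.3, G = 0.3, T = 0.2)))
    frags <- mspi_digest(ref, min_len = 10, max_len = 120)
    if (!nrow(frags)) next
    len <- frags$end - frags$start
    expect_true(all(len >= 10 & len <= 120))
    expect_true(all(diff(frags$start) > 0))
    expect_true(all(frags$start[-1] >= frags$end[-nrow(frags)]))
    # every boundary is a CCGG cut coordinate
    cuts <- gregexpr("CCGG", toupper(ref[["chr"]]))[[1]]
    expect_true(all(frags$start %in% cuts))
    expect_true(all(frags$end %in% cuts))
  }
})
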