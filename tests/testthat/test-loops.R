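test_that("BEDPE parsing canonicalizes anchors and reports bad lines", {
  path <- write_tmp(c("chr1\t100\t200\tchr1\t5000\t5100",
                      "chr2\t9000\t9100\tchr2\t100\t200\tloopX\t12"))
  loops <- read_bedpe(path)
  expect_equal(nrow(loops), 2L)
  # second record had its anchors out of genome order: normalized
  expect_equal(loops$start1[2], 100L)
  expect_equal(loops$start2[2], 9000L)
  expect_equal(loops$support[2], 12L)
  bad <- write_tmp(c("chr1\t100\t200\tchr1\t5000\t5100",
                     "chr1\t300\t250\tchr1\t600\t700"))
  expect_error(read_bedpe(bad), "line 2")
})

test_that("BEDPE round-trip preserves loops", {
  loops <- rand_loops(15, seed = 2)
  path <- tempfile(fileext = ".bedpe")
  write_bedpe(loops, path)
  back <- read_bedpe(path)
  expect_equal(back$start1, loops$start1)
  expect_equal(back$end2, loops$end2)
})

test_that("loop counting follows the one-count-per-loop anchor rule", {
  pk <- peak_set("chr1", 1000, 1400, name = "pk")
  # two distinct loops anchored on the peak -> stratum >=2
  l2 <- loop_set(c("chr1", "chr1"), c(1100, 1200), c(1300, 1350),
                 c("chr1", "chr1"), c(50000, 60000), c(50100, 60100))
  s2 <- loop_count_stratify(pk, l2)
  expect_equal(s2$loop_count, 2L)
  expect_equal(as.character(s2$stratum), ">=2")
  # one loop touching the peak with BOTH anchors still counts once
  l1 <- loop_set("chr1", 1100, 1200, "chr1", 1250, 1350)
  s1 <- loop_count_stratify(pk, l1)
  expect_equal(s1$loop_count, 1L)
  expect_equal(as.character(s1$stratum), "1")
  # no loops -> all zero
  s0 <- loop_count_stratify(pk, l1[0, ])
  expect_equal(as.character(s0$stratum), "0")
})

test_that("loop counts match the all-pairs oracle and strata partition the set", {
  for (trial in 1:20) {
    pks <- rand_peaks(30, seed = trial + 600)
    loops <- rand_loops(20, seed = trial + 700)
    strat <- loop_count_stratify(pks, loops)
    expect_equal(strat$loop_count, bf_loop_counts(pks, loops))
    expect_equal(sum(table(strat$stratum)), nrow(pks))
    # anchor order within a loop does not matter
    flipped <- loop_set(loops$chrom2, loops$start2, loops$end2,
                        loops$chrom1, loops$start1, loops$end1)
    expect_equal(loop_count_stratify(pks, flipped)$loop_count,
                 strat$loop_count)
  }
})

test_that("intensity comparison reports medians and flags empty strata", {
  pks <- peak_set(rep("chr1", 12), seq(1000, 12000, by = 1000),
                  seq(1000, 12000, by = 1000) + 400)
  strat <- data.frame(name = pks$name,
                      loop_count = rep(c(2L, 1L, 0L), each = 4),
                      stratum = factor(rep(c(">=2", "1", "0"), each = 4),
                                       levels = c("0", "1", ">=2")))
  rpkm <- data.frame(name = pks$name, rpkm = c(5, 6, 7, 8, 1, 2, 3, 4,
                                               1, 2, 3, 4))
  res <- compare_intensity_by_stratum(rpkm, strat)
  top <- res[res$group_a == ">=2" & res$group_b == "1", ]
  expect_equal(top$median_a, 6.5)
  # exact p for a clean separation of 4 vs 4: 2/C(8,4) = 2/70
  expect_equal(top$p, 2 / choose(8, 4), tolerance = 1e-12)
  # empty stratum propagates NA with warnings (one per affected comparison)
  strat2 <- strat; strat2$stratum[strat2$stratum == "0"] <- "1"
  warns <- testthat::capture_warnings(
    res2 <- compare_intensity_by_stratum(rpkm, strat2))
  expect_match(warns, "empty stratum", all = TRUE)
  expect_true(all(is.na(res2$p[res2$group_b == "0"])))
})

test_that("identical distributions across strata give p near 1", {
  set.seed(33)
  vals <- rnorm(300, 10)
  strat <- data.frame(name = sprintf("p%d", 1:300),
                      loop_count = rep(c(2L, 1L, 0L), 100),
                      stratum = factor(rep(c(">=2", "1", "0"), 100),
                                       levels = c("0", "1", ">=2")))
  rpkm <- data.frame(name = strat$name, rpkm = vals)
  res <- compare_intensity_by_stratum(rpkm, strat)
  expect_true(all(res$p > 0.05))
})

test_that("SE region I/O parses roles from the name field", {
  path <- write_tmp(c("chr1\t1000\t3000\tSE1:mother\t0\t.",
                      "chr1\t4000\t5000\tSE1:daughter\t0\t."))
  se <- read_se_regions(path)
  expect_equal(se$role, c("mother", "daughter"))
  expect_equal(se$se_id, c("SE1", "SE1"))
  bad <- write_tmp("chr1\t0\t10\tnope")
  expect_error(read_se_regions(bad), "SEid:role")
  rt <- tempfile(fileext = ".bed")
  write_se_regions(se, rt)
  expect_equal(read_se_regions(rt)$role, se$role)
})

test_that("SE occupancy requires a loop-associated peak, not any peak", {
  se <- se_region_set(c("chr1", "chr1", "chr1", "chr1"),
                      c(1000, 10000, 20000, 30000),
                      c(3000, 12000, 22000, 32000),
                      se_id = c("SE1", "SE2", "SE1", "SE2"),
                      role = c("mother", "mother", "daughter", "daughter"))
  pks <- peak_set(c("chr1", "chr1", "chr1"), c(1500, 10500, 20500),
                  c(1900, 10900, 20900))
  # only the first peak carries a loop
  loops <- loop_set("chr1", 1600, 1800, "chr1", 90000, 91000)
  strat <- loop_count_stratify(pks, loops)
  frac <- se_overlap_fraction(se, pks, strat)
  expect_equal(frac$percent[frac$role == "mother"], 50)
  expect_equal(frac$percent[frac$role == "daughter"], 0)
  # with no loops at all both roles drop to zero
  frac0 <- se_overlap_fraction(se, pks, loop_count_stratify(pks, loops[0, ]))
  expect_equal(frac0$percent, c(0, 0))
  # adding loops can only increase the fractions
  more <- loop_set(c("chr1", "chr1"), c(1600, 20600), c(1800, 20800),
                   c("chr1", "chr1"), c(90000, 95000), c(91000, 96000))
  frac2 <- se_overlap_fraction(se, pks, loop_count_stratify(pks, more))
  expect_true(all(frac2$percent >= frac$percent))
})

test_that("a missing role class is an error naming the role", {
  se <- se_region_set("chr1", 1000, 3000, se_id = "SE1", role = "mother")
  pks <- peak_set("chr1", 1500, 1900)
  strat <- loop_count_stratify(pks, loop_set("chr1", 1600, 1800,
                                             "chr1", 90000, 91000))
  expect_error(se_overlap_fraction(se, pks, strat), "daughter")
})
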