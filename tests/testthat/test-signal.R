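test_that("pileup counts single and multi-bin fragments correctly", {
  fr <- fragment_set("chr1", 10, 20)
  win <- list(chrom = "chr1", start = 0L, end = 30L)
  expect_equal(pileup_coverage(fr, win, bin = 10), c(0L, 1L, 0L))
  fr2 <- fragment_set("chr1", 5, 25)
  expect_equal(pileup_coverage(fr2, win, bin = 10), c(1L, 1L, 1L))
  expect_error(pileup_coverage(fr, win, bin = 7), "does not divide")
})

test_that("pileup matches naive per-bin fragment counting on random tracks", {
  for (trial in 1:15) {
    fr <- rand_frags(100, seed = trial)
    win <- list(chrom = "chr1", start = 200L, end = 1200L)
    bin <- sample(c(10L, 50L, 100L), 1)
    expect_equal(pileup_coverage(fr, win, bin), bf_pileup(fr, win, bin))
  }
})

test_that("symmetric fragment placement yields a symmetric density profile", {
  pk <- peak_set("chr1", 4500, 5501, summit = 5000)
  offs <- c(-300, -150, -40, 40, 150, 300)   # mirror pairs around the summit
  fr <- fragment_set(rep("chr1", 6), 5000 + offs - 50, 5000 + offs + 50)
  prof <- tag_density_profile(pk, fr, flank = 500, bin = 10)
  expect_equal(prof$values, rev(prof$values))
  expect_equal(length(prof$values), 100L)
})

test_that("an empty track gives an all-zero profile and empty peaks error", {
  pk <- peak_set("chr1", 4500, 5501, summit = 5000)
  fr <- fragment_set("chr2", 0, 100)   # nothing on chr1
  prof <- tag_density_profile(pk, fr, flank = 500, bin = 10)
  expect_true(all(prof$values == 0))
  empty <- peak_set(character(0), integer(0), integer(0))
  expect_error(tag_density_profile(empty, fr), "no peaks to profile")
})

test_that("tag density scales with fragments but not with library depth", {
  pk <- peak_set("chr1", 4500, 5501, summit = 5000)
  set.seed(11)
  centers <- 5000 + sample(-400:400, 200, replace = TRUE)
  fr <- fragment_set(rep("chr1", 200), centers - 100, centers + 100)
  prof <- tag_density_profile(pk, fr, flank = 500, bin = 10)
  # duplicating every fragment (library doubles too) leaves density invariant
  fr2 <- fragment_set(rep("chr1", 400), rep(centers - 100, 2),
                      rep(centers + 100, 2))
  prof2 <- tag_density_profile(pk, fr2, flank = 500, bin = 10)
  expect_equal(prof2$values, prof$values)
  # doubling fragments at a fixed library size doubles density
  fr3 <- fr2; fr3$library_size <- fr$library_size
  prof3 <- tag_density_profile(pk, fr3, flank = 500, bin = 10)
  expect_equal(prof3$values, 2 * prof$values)
})

test_that("profile values equal the mean of per-peak brute-force vectors", {
  pks <- peak_set(rep("chr1", 10), seq(10000, 100000, by = 10000) - 500,
                  seq(10000, 100000, by = 10000) + 501,
                  summit = seq(10000, 100000, by = 10000))
  set.seed(21)
  anchor <- rep(pks$summit, each = 100)
  centers <- anchor + sample(-600:600, 1000, replace = TRUE)
  fr <- fragment_set(rep("chr1", 1000), pmax(0, centers - 100), centers + 100)
  prof <- tag_density_profile(pks, fr, flank = 500, bin = 10)
  per_peak <- sapply(seq_len(nrow(pks)), function(i) {
    win <- list(chrom = "chr1", start = pks$summit[i] - 500L,
                end = pks$summit[i] + 500L)
    bf_pileup(fr, win, 10L)
  })
  expect_equal(prof$values, rowMeans(per_peak) * 1e7 / fr$library_size)
})

test_that("summit RPKM follows the fixed 101-bp window formula", {
  pk <- peak_set("chr1", 900, 1101, summit = 1000)
  fr <- fragment_set(rep("chr1", 10), rep(980, 10), rep(1020, 10))
  fr$library_size <- 1e6
  rp <- rpkm_summit(pk, fr)
  expect_equal(rp$count, 10L)
  expect_equal(rp$rpkm, 10 / (0.101 * 1))
  # no overlapping fragments -> 0
  far <- fragment_set("chr1", 5000, 5100)
  expect_equal(rpkm_summit(pk, far)$rpkm, 0)
  # RPKM ignores peak width: same summit, wider peak, same value
  wide <- peak_set("chr1", 0, 4000, summit = 1000)
  expect_equal(rpkm_summit(wide, fr)$rpkm, rp$rpkm)
})

test_that("summit RPKM counts agree with one-by-one window counting", {
  for (trial in 1:10) {
    pks <- rand_peaks(20, seed = trial + 300, n_chrom = 1L)
    fr <- rand_frags(500, seed = trial + 400, glen = 1e5)
    rp <- rpkm_summit(pks, fr)
    win <- summit_window(pks$summit, 50)
    manual <- vapply(seq_len(nrow(pks)), function(i) {
      bf_window_count(fr, pks$chrom[i], win$start[i], win$end[i])
    }, integer(1))
    expect_equal(rp$count, manual)
    expect_equal(rp$rpkm, manual / (0.101 * fr$library_size / 1e6))
  }
})

test_that("library size zero is rejected", {
  pk <- peak_set("chr1", 900, 1101, summit = 1000)
  fr <- fragment_set("chr1", 980, 1020)
  fr$library_size <- 0
  expect_error(rpkm_summit(pk, fr), "library size")
})

test_that("heatmap rows sort by total signal and average back to the profile", {
  pks <- peak_set(rep("chr1", 2), c(9500, 19500), c(10501, 20501),
                  name = c("weak", "strong"), summit = c(10000, 20000))
  fr <- fragment_set(rep("chr1", 30),
                     c(rep(9950, 10), rep(19950, 20)),
                     c(rep(10050, 10), rep(20050, 20)))
  m <- heatmap_matrix(pks, fr, flank = 1000, bin = 25)
  expect_equal(rownames(m), c("strong", "weak"))
  prof <- tag_density_profile(pks, fr, flank = 1000, bin = 25)
  expect_equal(unname(colMeans(m)), prof$values)
  # single peak: matrix row equals its own pileup vector (normalized)
  one <- structure(as.data.frame(pks)[1, ], class = c("PeakSet", "data.frame"),
                   label = "one")
  m1 <- heatmap_matrix(one, fr, flank = 1000, bin = 25)
  win <- list(chrom = "chr1", start = 10000L - 1000L, end = 10000L + 1000L)
  expect_equal(unname(m1[1, ]),
               bf_pileup(fr, win, 25L) * 1e7 / fr$library_size)
})

test_that("left-clipped windows are dropped with a warning", {
  pks <- peak_set(c("chr1", "chr1"), c(0, 9500), c(200, 10501),
                  summit = c(100, 10000))
  fr <- fragment_set("chr1", 9900, 10100)
  expect_warning(prof <- tag_density_profile(pks, fr, flank = 500, bin = 10),
                 "left-clipped")
  expect_equal(prof$n_peaks, 1L)
})
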