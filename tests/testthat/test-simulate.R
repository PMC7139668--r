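small_cistrome_cfg <- function(n_a = 40, n_b = 30, n_shared = 15) {
  structure(list(n_a = n_a, n_b = n_b, n_shared = n_shared, peak_width = 400,
                 spacing = 3000, n_chrom = 2, chrom_len = 3e6, seed = 99,
                 label_a = "A", label_b = "B",
                 frag_len = 200, frag_flank = 200, frag_mean_shared = 40,
                 frag_mean_only = 8, frag_background = 50),
            class = "fixture_config")
}

test_that("generated cistromes realize the designed overlap exactly", {
  cfg <- small_cistrome_cfg()
  cs <- gen_cistrome(cfg)
  part <- overlap_partition(cs$a, cs$b)
  expect_equal(nrow(part$shared_b), 15L)
  expect_equal(nrow(part$shared_a), 15L)
  expect_setequal(part$shared_b$name,
                  cs$truth$name[cs$truth$set == "b" & cs$truth$class == "shared"])
  # degenerate designs
  none <- gen_cistrome(small_cistrome_cfg(n_shared = 0))
  expect_equal(nrow(overlap_partition(none$a, none$b)$shared_a), 0L)
  all_sh <- gen_cistrome(small_cistrome_cfg(n_a = 20, n_b = 20, n_shared = 20))
  expect_equal(shared_fraction(overlap_partition(all_sh$a, all_sh$b), "b"), 100)
})

test_that("factor-specific peaks stay over 1 kb from the other cistrome", {
  cs <- gen_cistrome(small_cistrome_cfg())
  only_a <- cs$a[cs$truth$class[cs$truth$set == "a"] == "only", ]
  for (i in seq_len(nrow(only_a))) {
    same <- cs$b[cs$b$chrom == only_a$chrom[i], ]
    if (nrow(same)) {
      gap <- pmax(same$start - only_a$end[i], only_a$start[i] - same$end)
      expect_true(all(gap > 1000))
    }
  }
})

test_that("an overfull design errors with a genome-size suggestion", {
  cfg <- small_cistrome_cfg(n_a = 2000, n_b = 2000, n_shared = 10)
  cfg$n_chrom <- 1; cfg$chrom_len <- 1e5
  expect_error(gen_cistrome(cfg), "toy genome too small")
})

test_that("generators are deterministic given (config, seed)", {
  cfg <- small_cistrome_cfg()
  expect_identical(gen_cistrome(cfg), gen_cistrome(cfg))
  cs <- gen_cistrome(cfg)
  cls <- cs$truth$class[cs$truth$set == "b"]
  expect_identical(gen_fragments(cfg, cs$b, cls), gen_fragments(cfg, cs$b, cls))
  # different seeds move the peaks
  expect_false(identical(gen_cistrome(cfg)$a$start,
                         gen_cistrome(cfg, seed = 1)$a$start))
})

test_that("fragment piles reproduce the designed class intensity ordering", {
  cfg <- small_cistrome_cfg()
  cs <- gen_cistrome(cfg)
  cls <- cs$truth$class[cs$truth$set == "b"]
  frags <- gen_fragments(cfg, cs$b, cls)
  sh <- structure(as.data.frame(cs$b)[cls == "shared", ],
                  class = c("PeakSet", "data.frame"), label = "B")
  on <- structure(as.data.frame(cs$b)[cls == "only", ],
                  class = c("PeakSet", "data.frame"), label = "B")
  p_sh <- tag_density_profile(sh, frags)
  p_on <- tag_density_profile(on, frags)
  expect_gt(mean(p_sh$values), mean(p_on$values))
  center <- which.min(abs(p_sh$offsets))
  expect_gt(p_sh$values[center], p_on$values[center])
  # empty design yields an empty track
  cfg0 <- small_cistrome_cfg()
  cfg0$frag_mean_shared <- 0; cfg0$frag_mean_only <- 0; cfg0$frag_background <- 0
  expect_equal(gen_fragments(cfg0, cs$b, cls)$library_size, 0L)
})

test_that("sequence classes carry exact embed counts and clean backgrounds", {
  cfg <- structure(list(motif = "GATA3", n_per_class = 150, embed_shared = 45,
                        embed_only = 12, seq_len = 100, gc = 0.41,
                        max_retry = 1000, seed = 3),
                   class = "fixture_config")
  sq <- gen_sequences(cfg)
  expect_equal(percent_of_targets(sq$pwm, sq$shared)$percent, 100 * 45 / 150)
  expect_equal(percent_of_targets(sq$pwm, sq$only)$percent, 100 * 12 / 150)
  expect_true(all(nchar(sq$shared) == 100))
  # truth table matches the scanner verdict sequence by sequence
  tt <- sq$truth[sq$truth$class == "shared", ]
  expect_equal(percent_of_targets(sq$pwm, sq$shared)$hit, tt$embedded)
  # degenerate embeds
  cfg$embed_shared <- 0; cfg$embed_only <- 150
  sq2 <- gen_sequences(cfg)
  expect_equal(percent_of_targets(sq2$pwm, sq2$shared)$percent, 0)
  expect_equal(percent_of_targets(sq2$pwm, sq2$only)$percent, 100)
  expect_identical(gen_sequences(cfg), gen_sequences(cfg))
})

test_that("SE/loop fixtures realize designed fractions for any seed", {
  cfg <- structure(list(n_mother = 40, looped_mother = 13, n_daughter = 60,
                        looped_daughter = 9, mother_width = 2000,
                        daughter_width = 1000, peak_width = 400,
                        spacing = 6000, n_chrom = 4, chrom_len = 3e6,
                        n_strata2 = 10, n_strata1 = 15, n_strata0 = 20,
                        seed = 17),
                   class = "fixture_config")
  for (sd in c(17, 3, 12345)) {
    sim <- gen_loops_and_se(cfg, seed = sd)
    strat <- loop_count_stratify(sim$peaks, sim$loops)
    frac <- se_overlap_fraction(sim$se, sim$peaks, strat)
    expect_equal(frac$percent[frac$role == "mother"],
                 round(100 * 13 / 40, 2))
    expect_equal(frac$percent[frac$role == "daughter"],
                 round(100 * 9 / 60, 2))
    # designed strata realized on the standalone peaks
    tab <- table(sim$classes, strat$stratum)
    expect_equal(unname(tab["strata2", ">=2"]), 10)
    expect_equal(unname(tab["strata1", "1"]), 15)
    expect_equal(unname(tab["strata0", "0"]), 20)
  }
  # no loops at all: both fractions zero
  sim <- gen_loops_and_se(cfg)
  strat0 <- loop_count_stratify(sim$peaks, sim$loops[0, ])
  frac0 <- se_overlap_fraction(sim$se, sim$peaks, strat0)
  expect_equal(frac0$percent, c(0, 0))
  # every region looped: both fractions 100
  cfg2 <- cfg; cfg2$looped_mother <- 40; cfg2$looped_daughter <- 60
  sim2 <- gen_loops_and_se(cfg2)
  frac2 <- se_overlap_fraction(sim2$se, sim2$peaks,
                               loop_count_stratify(sim2$peaks, sim2$loops))
  expect_equal(frac2$percent, c(100, 100))
})

test_that("designed DE truth is recovered independently of the seed", {
  cfg <- structure(list(n_genes = 300, n_per_group = 6, base_mean = 500,
                        dispersion = 0.01, n_down = 40, n_up = 55,
                        log2fc = 2, n_se = 30, n_se_de = 12, seed = 9),
                   class = "fixture_config")
  for (sd in c(9, 77)) {
    sim <- gen_counts_matrix(cfg, seed = sd)
    res <- de_test(sim$counts, sim$groups)
    filt <- de_filter(res)
    expect_setequal(filt$down, sim$truth$gene[sim$truth$status == "down"])
    expect_setequal(filt$up, sim$truth$gene[sim$truth$status == "up"])
    sec <- se_gene_de_count(filt$results, sim$truth$gene[sim$truth$se_flag])
    expect_equal(sec$n_se, 30L)
    expect_equal(sec$n_se_de, 12L)
  }
  expect_identical(gen_counts_matrix(cfg), gen_counts_matrix(cfg))
  # zero designed effects give zero calls
  cfg0 <- cfg; cfg0$n_down <- 0; cfg0$n_up <- 0; cfg0$n_se_de <- 0
  sim0 <- gen_counts_matrix(cfg0)
  filt0 <- de_filter(de_test(sim0$counts, sim0$groups))
  expect_length(filt0$down, 0)
  expect_length(filt0$up, 0)
})

test_that("survival generator honors censoring settings and determinism", {
  cfg <- structure(list(n_per_arm = 50, base_hazard = 0.02, hazard_ratio = 2,
                        censor_max = 0, seed = 21), class = "fixture_config")
  cohort <- gen_survival(cfg)
  expect_true(all(cohort$event == 1))   # censoring disabled
  expect_identical(gen_survival(cfg), gen_survival(cfg))
  cfg$censor_max <- 30
  expect_gt(sum(gen_survival(cfg)$event == 0), 0)
})
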