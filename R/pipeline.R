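# End-to-end orchestration: run every analysis stage on the packaged (or
# user-supplied) fixture configurations and write a deterministic report of
# all recovered quantities.

.default_pipeline_config <- function() {
  list(fixtures = list(cistrome = "mcf7_like", motif = "motif_freq",
                       loops = "se_loops", de = "de_se_genes"),
       survival = list(n_per_arm = 200, base_hazard = 0.02,
                       hazard_ratio = 3, censor_max = 120, seed = 707),
       stages = c("cistrome", "signal", "motif", "loops", "de", "survival"),
       min_overlap = 1, profile_flank = 500, profile_bin = 10,
       rpkm_flank = 50, fc_min = 1.5, fdr_max = 0.01, min_loops = 1,
       split_quantile = 0.5, seed = NULL)
}

#' Run the integrative cistrome analysis pipeline
#'
#' Executes the analysis stages in order on synthetic inputs generated from
#' fixture configurations: occupancy partitioning of the two cistromes,
#' summit-centered signal profiling per occupancy class, known-motif
#' percent-of-target and enrichment, chromatin-loop stratification with
#' super-enhancer mother/daughter occupancy, differential-expression
#' filtering with SE-gene intersection, and the survival comparison. The
#' run is deterministic given the configuration: re-running writes
#' byte-identical report files.
#'
#' @param config optional list (or path to a YAML file) overriding the
#'   defaults: fixture names/paths per stage, \code{stages} to run,
#'   thresholds (\code{min_overlap}, \code{profile_flank},
#'   \code{profile_bin}, \code{rpkm_flank}, \code{fc_min}, \code{fdr_max},
#'   \code{min_loops}, \code{split_quantile}), an optional
#'   \code{loops_bedpe} path replacing the generated loops, and an optional
#'   \code{seed} overriding every fixture seed.
#' @param out_dir directory for \code{report.tsv} and \code{summary.txt};
#'   created if missing. \code{NULL} skips writing.
#' @return invisibly, a data frame with columns \code{stage},
#'   \code{metric}, \code{value}.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.default_pipeline_config(), config)
  rows <- list()
  note <- function(stage, metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(stage = stage, metric = metric,
                                             value = value,
                                             stringsAsFactors = FALSE)
  }
  fmt <- function(x, digits = 4L) {
    if (is.character(x)) x else formatC(x, digits = digits, format = "f")
  }
  seed_of <- function(fx) if (is.null(cfg$seed)) fx$seed else cfg$seed
  summary_lines <- character(0)
  say <- function(...) {
    summary_lines <<- c(summary_lines, sprintf(...))
    invisible(NULL)
  }

  run_stage <- function(stage, body) {
    if (!stage %in% cfg$stages) return(invisible(NULL))
    tryCatch(body(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  cistrome <- NULL
  run_stage("cistrome", function() {
    fx <- read_fixture_config(cfg$fixtures$cistrome)
    cistrome <<- gen_cistrome(fx, seed = seed_of(fx))
    part <- overlap_partition(cistrome$a, cistrome$b,
                              min_overlap = cfg$min_overlap)
    note("cistrome", paste0("n_", set_label(cistrome$a)),
         fmt(nrow(cistrome$a), 0))
    note("cistrome", paste0("n_", set_label(cistrome$b)),
         fmt(nrow(cistrome$b), 0))
    note("cistrome", "shared_fraction_a_pct", fmt(shared_fraction(part, "a"), 2))
    note("cistrome", "shared_fraction_b_pct", fmt(shared_fraction(part, "b"), 2))
    say("[cistrome] %s: %d peaks, %s: %d peaks (min_overlap = %d bp)",
        set_label(cistrome$a), nrow(cistrome$a), set_label(cistrome$b),
        nrow(cistrome$b), as.integer(cfg$min_overlap))
    say("[cistrome] shared fraction: %s %.2f%%, %s %.2f%%",
        set_label(cistrome$a), shared_fraction(part, "a"),
        set_label(cistrome$b), shared_fraction(part, "b"))
  })

  run_stage("signal", function() {
    if (is.null(cistrome)) stop("signal stage needs the cistrome stage")
    fx <- read_fixture_config(cfg$fixtures$cistrome)
    cls_b <- cistrome$truth$class[cistrome$truth$set == "b"]
    frags <- gen_fragments(fx, cistrome$b, cls_b, seed = seed_of(fx),
                           label = set_label(cistrome$b))
    for (cl in c("shared", "only")) {
      sel <- .subset_peaks(cistrome$b, which(cls_b == cl))
      prof <- tag_density_profile(sel, frags, flank = cfg$profile_flank,
                                  bin = cfg$profile_bin)
      center <- prof$values[which.min(abs(prof$offsets))]
      note("signal", sprintf("density_at_summit_%s", cl), fmt(center, 4))
      say("[signal] %s %s peaks: tag density at summit %.3f (n = %d)",
          set_label(cistrome$b), cl, center, prof$n_peaks)
    }
  })

  run_stage("motif", function() {
    fx <- read_fixture_config(cfg$fixtures$motif)
    seqs <- gen_sequences(fx, seed = seed_of(fx))
    pot_only <- percent_of_targets(seqs$pwm, seqs$only)
    pot_shared <- percent_of_targets(seqs$pwm, seqs$shared)
    enr <- motif_enrichment_test(seqs$pwm, seqs$shared, seqs$only)
    note("motif", "percent_of_target_only_pct", fmt(pot_only$percent, 2))
    note("motif", "percent_of_target_shared_pct", fmt(pot_shared$percent, 2))
    note("motif", "enrichment_p", fmt(enr$p, 3))
    say("[motif] %s percent-of-target: only %.2f%%, shared %.2f%% (p = %.3g %s)",
        seqs$pwm$name, pot_only$percent, pot_shared$percent, enr$p,
        signif_stars(enr$p))
  })

  run_stage("loops", function() {
    fx <- read_fixture_config(cfg$fixtures$loops)
    sim <- gen_loops_and_se(fx, seed = seed_of(fx))
    loops <- if (!is.null(cfg$loops_bedpe)) read_bedpe(cfg$loops_bedpe)
    else sim$loops
    strat <- loop_count_stratify(sim$peaks, loops)
    sizes <- table(strat$stratum)
    for (s in names(sizes)) {
      note("loops", sprintf("stratum_%s_n", s), fmt(as.integer(sizes[[s]]), 0))
    }
    frags <- gen_fragments(fx, sim$peaks, sim$classes, seed = seed_of(fx),
                           label = "NR2F2")
    rp <- rpkm_summit(sim$peaks, frags, flank = cfg$rpkm_flank)
    mw <- compare_intensity_by_stratum(rp, strat)
    for (i in seq_len(nrow(mw))) {
      note("loops", sprintf("mw_p_%s_vs_%s", mw$group_a[i], mw$group_b[i]),
           fmt(mw$p[i], 6))
    }
    sef <- se_overlap_fraction(sim$se, sim$peaks, strat,
                               min_loops = cfg$min_loops)
    for (i in seq_len(nrow(sef))) {
      note("loops", sprintf("se_%s_pct", sef$role[i]), fmt(sef$percent[i], 2))
    }
    say("[loops] strata sizes: >=2: %d, 1: %d, 0: %d",
        as.integer(sizes[[">=2"]]), as.integer(sizes[["1"]]),
        as.integer(sizes[["0"]]))
    say("[loops] SE occupancy by loop-associated peaks: mothers %.2f%%, daughters %.2f%%",
        sef$percent[sef$role == "mother"], sef$percent[sef$role == "daughter"])
  })

  run_stage("de", function() {
    fx <- read_fixture_config(cfg$fixtures$de)
    sim <- gen_counts_matrix(fx, seed = seed_of(fx))
    res <- de_test(sim$counts, sim$groups)
    filt <- de_filter(res, fc_min = cfg$fc_min, fdr_max = cfg$fdr_max)
    sec <- se_gene_de_count(filt$results,
                            sim$truth$gene[sim$truth$se_flag])
    note("de", "n_down", fmt(length(filt$down), 0))
    note("de", "n_up", fmt(length(filt$up), 0))
    note("de", "n_se", fmt(sec$n_se, 0))
    note("de", "n_se_de", fmt(sec$n_se_de, 0))
    say("[de] %d downregulated, %d upregulated (FC >= %.2g, FDR < %.2g)",
        length(filt$down), length(filt$up), cfg$fc_min, cfg$fdr_max)
    say("[de] SE-associated genes differentially expressed: %d/%d",
        sec$n_se_de, sec$n_se)
  })

  run_stage("survival", function() {
    sv <- cfg$survival
    fx <- structure(sv, class = "fixture_config")
    cohort <- gen_survival(fx, seed = seed_of(fx))
    grp <- median_split(cohort$expression_z, quantile = cfg$split_quantile)
    lr <- logrank_test(cohort$time, cohort$event, grp)
    note("survival", "logrank_chi2", fmt(lr$chi2, 4))
    note("survival", "logrank_p", fmt(lr$p, 6))
    say("[survival] logrank chi2 = %.2f, p = %.3g %s (high vs low expression)",
        lr$chi2, lr$p, signif_stars(lr$p))
  })

  report <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(c("stage\tmetric\tvalue",
                 sprintf("%s\t%s\t%s", report$stage, report$metric,
                         report$value)),
               file.path(out_dir, "report.tsv"))
    writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  }
  invisible(report)
}
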