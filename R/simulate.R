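# Synthetic-data generators with constructed ground truth: toy cistromes
# with an exact overlap design, fragment piles enriched at summits,
# motif-bearing 100 bp sequences with certified hit-free backgrounds,
# super-enhancer mother/daughter regions with loops at exact fractions,
# negative-binomial count matrices with designed differential expression,
# and two-group survival cohorts. Every generator is a pure function of
# (config, seed): re-running with the same arguments reproduces the output
# exactly, and the designed fractions/counts are recovered exactly for any
# seed by construction.

#' Read a fixture configuration
#'
#' Fixture configurations are flat \code{key = value} text files; the four
#' packaged fixtures (\code{mcf7_like}, \code{motif_freq}, \code{se_loops},
#' \code{de_se_genes}) encode the designed overlap structure, motif-embed
#' counts, loop placement counts and differential-expression design,
#' together with a fixed seed. Numeric values are parsed as numbers.
#'
#' @param name a packaged fixture name or a path to a config file.
#' @return named list of class \code{fixture_config}.
#' @export
read_fixture_config <- function(name) {
  path <- if (file.exists(name)) name else {
    system.file("extdata", "fixtures", paste0(name, ".cfg"),
                package = "cistroflow")
  }
  .assert(nzchar(path) && file.exists(path), "fixture config not found: %s", name)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[[`, character(1L), 1L)
  vals <- lapply(kv, function(x) {
    v <- x[[2L]]
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  })
  structure(stats::setNames(vals, keys), class = "fixture_config")
}

# Deterministic slot layout on a toy genome: `n` site anchor positions,
# `spacing` bp apart, across `n_chrom` chromosomes of `chrom_len` bp.
.genome_slots <- function(n, spacing, n_chrom, chrom_len) {
  per_chrom <- chrom_len %/% spacing
  if (per_chrom * n_chrom < n) {
    stop(sprintf(paste0("toy genome too small: %d slots needed, %d available; ",
                        "increase chrom_len or n_chrom"),
                 n, per_chrom * n_chrom), call. = FALSE)
  }
  idx <- seq_len(n) - 1L
  list(chrom = sprintf("chr%d", idx %/% per_chrom + 1L),
       base = (idx %% per_chrom) * spacing)
}

#' Generate two cistromes with an exact overlap design
#'
#' Places \code{n_shared} overlapping peak pairs (>= 1 bp intersection)
#' and \code{n_a - n_shared} / \code{n_b - n_shared} factor-specific peaks
#' separated by more than 1 kb from every peak of the other set, so the
#' occupancy partition recovers the designed shared fraction exactly for
#' any seed. Peak placement (slot shuffling and jitter) is deterministic
#' given the seed.
#'
#' @param cfg a \code{fixture_config} with \code{n_a}, \code{n_b},
#'   \code{n_shared}, \code{peak_width}, \code{spacing}, \code{n_chrom},
#'   \code{chrom_len}, labels \code{label_a}/\code{label_b}, \code{seed}.
#' @param seed RNG seed; defaults to the one recorded in the config.
#' @return list with \code{PeakSet}s \code{a} and \code{b} and a
#'   \code{truth} data frame (name, set, class).
#' @export
gen_cistrome <- function(cfg, seed = cfg$seed) {
  n_a <- cfg$n_a; n_b <- cfg$n_b; n_shared <- cfg$n_shared
  .assert(n_shared <= min(n_a, n_b), "n_shared cannot exceed either set size")
  w <- cfg$peak_width %||% 400
  spacing <- cfg$spacing %||% 3000
  shift <- ceiling(w * 0.375)          # shared partner offset: >= 1 bp overlap
  span <- w + shift
  .assert(spacing >= span + 1200,
          "spacing too small for the peak width: specific peaks must stay > 1 kb apart")
  n_slots <- n_a + n_b - n_shared
  slots <- .genome_slots(n_slots, spacing, cfg$n_chrom %||% 4, cfg$chrom_len %||% 3e6)
  .with_seed(seed, {
    ord <- sample.int(n_slots)
    jit <- sample.int(spacing - span - 1000L, n_slots, replace = TRUE) - 1L
  })
  chrom <- slots$chrom[ord]; start <- slots$base[ord] + jit
  cls <- rep(c("shared", "only_a", "only_b"),
             c(n_shared, n_a - n_shared, n_b - n_shared))
  i_sh <- which(cls == "shared"); i_a <- which(cls == "only_a")
  i_b <- which(cls == "only_b")
  a <- peak_set(chrom = chrom[c(i_sh, i_a)],
                start = start[c(i_sh, i_a)],
                end = start[c(i_sh, i_a)] + w,
                name = sprintf("%s_%d", cfg$label_a %||% "A", seq_len(n_a)),
                label = cfg$label_a %||% "A")
  b_start <- c(start[i_sh] + shift, start[i_b])
  b <- peak_set(chrom = chrom[c(i_sh, i_b)], start = b_start,
                end = b_start + w,
                name = sprintf("%s_%d", cfg$label_b %||% "B", seq_len(n_b)),
                label = cfg$label_b %||% "B")
  truth <- data.frame(
    name = c(a$name, b$name),
    set = rep(c("a", "b"), c(n_a, n_b)),
    class = c(rep(c("shared", "only"), c(n_shared, n_a - n_shared)),
              rep(c("shared", "only"), c(n_shared, n_b - n_shared))),
    stringsAsFactors = FALSE)
  list(a = a, b = b, truth = truth)
}

#' Generate fragment piles around peak summits
#'
#' Emits pre-extended fragments centered near each summit with
#' class-dependent Poisson fragment counts (keys \code{frag_mean_<class>}
#' in the config) plus uniform background fragments, emulating stronger
#' ChIP signal at one peak class than another.
#'
#' @param cfg a \code{fixture_config} with \code{frag_len},
#'   \code{frag_flank}, \code{frag_background}, \code{frag_mean_<class>}
#'   entries, \code{n_chrom}, \code{chrom_len} and \code{seed}.
#' @param peaks a \code{PeakSet} with summits.
#' @param classes character vector of per-peak class labels.
#' @param seed RNG seed; defaults to the config's.
#' @param label track name.
#' @return a \code{FragmentSet}.
#' @export
gen_fragments <- function(cfg, peaks, classes, seed = cfg$seed,
                          label = "fragments") {
  .assert(length(classes) == nrow(peaks), "one class label per peak")
  len <- cfg$frag_len %||% 200
  flank <- cfg$frag_flank %||% 200
  means <- vapply(classes, function(cl) {
    m <- cfg[[paste0("frag_mean_", cl)]]
    .assert(!is.null(m), "config lacks frag_mean_%s", cl)
    m
  }, numeric(1L))
  .with_seed(seed + 1L, {
    k <- stats::rpois(nrow(peaks), means)
    centers <- rep(peaks$summit, k) +
      sample(seq(-flank, flank), sum(k), replace = TRUE)
    chrom <- rep(peaks$chrom, k)
    n_bg <- stats::rpois(1L, cfg$frag_background %||% 0)
    if (n_bg > 0) {
      chrom <- c(chrom, sprintf("chr%d", sample.int(cfg$n_chrom %||% 4, n_bg,
                                                    replace = TRUE)))
      centers <- c(centers, sample.int((cfg$chrom_len %||% 3e6) - len, n_bg))
    }
  })
  start <- pmax(0L, as.integer(centers) - as.integer(len %/% 2))
  fragment_set(chrom, start, start + as.integer(len), label = label)
}

#' Generate motif-bearing sequence classes with hit-free backgrounds
#'
#' For each class, exactly the configured number of sequences carry one
#' embedded consensus instance of the configured motif at a random offset;
#' every remaining sequence is rejection-sampled until it contains no hit
#' at the scanner's default threshold on either strand. Percent-of-target
#' over a class is therefore exact by construction: 100 * embeds / n.
#'
#' @param cfg a \code{fixture_config} with \code{motif},
#'   \code{n_per_class}, \code{embed_shared}, \code{embed_only},
#'   \code{seq_len} (100), \code{gc}, \code{max_retry}, \code{seed}.
#' @param seed RNG seed; defaults to the config's.
#' @return list with named character vectors \code{shared} and \code{only},
#'   the \code{PWM} used, and a \code{truth} data frame.
#' @export
gen_sequences <- function(cfg, seed = cfg$seed) {
  pwm <- load_motif_pwms()[[cfg$motif %||% "GATA3"]]
  .assert(!is.null(pwm), "motif '%s' not in the packaged library", cfg$motif)
  n <- cfg$n_per_class
  L <- cfg$seq_len %||% 100
  gc <- cfg$gc %||% 0.41
  base_p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  cons <- match(strsplit(pwm_consensus(pwm), "")[[1L]], .BASES)
  embeds <- c(shared = cfg$embed_shared, only = cfg$embed_only)
  out <- list()
  truths <- list()
  .with_seed(seed + 2L, {
    for (cl in names(embeds)) {
      ne <- embeds[[cl]]
      .assert(ne >= 0 && ne <= n, "embed count must lie in [0, n]")
      codes <- matrix(sample.int(4L, n * L, replace = TRUE, prob = base_p),
                      nrow = n, ncol = L)
      emb <- seq_len(ne)                 # rows carrying an embedded instance
      offs <- integer(n)
      if (ne > 0) {
        offs[emb] <- sample.int(L - pwm$width + 1L, ne, replace = TRUE) - 1L
        for (j in seq_along(cons)) codes[cbind(emb, offs[emb] + j)] <- cons[j]
      }
      bg <- setdiff(seq_len(n), emb)     # certify backgrounds hit-free
      tries <- 0L
      repeat {
        bad <- bg[.scan_any_hit(pwm, codes[bg, , drop = FALSE])]
        if (!length(bad)) break
        tries <- tries + 1L
        if (tries > (cfg$max_retry %||% 1000)) {
          stop("rejection sampling exceeded max_retry; raise the hit threshold",
               call. = FALSE)
        }
        codes[bad, ] <- sample.int(4L, length(bad) * L, replace = TRUE,
                                   prob = base_p)
      }
      seqs <- apply(codes, 1L, function(r) paste(.BASES[r], collapse = ""))
      names(seqs) <- sprintf("%s_seq_%d", cl, seq_len(n))
      out[[cl]] <- seqs
      truths[[cl]] <- data.frame(name = names(seqs), class = cl,
                                 embedded = seq_len(n) <= ne,
                                 offset = ifelse(seq_len(n) <= ne, offs, NA),
                                 stringsAsFactors = FALSE)
    }
  })
  list(shared = out$shared, only = out$only, pwm = pwm,
       truth = do.call(rbind, truths))
}

#' Generate super-enhancer regions, loops and a stratified peak set
#'
#' Builds mother and daughter super-enhancer regions of which exactly the
#' configured numbers receive a peak anchored by a chromatin loop (the
#' remaining regions receive either a loop-free peak or no peak), plus
#' standalone peaks populating the >=2 / 1 / 0 interaction strata. Loop
#' second anchors land in a dedicated anchor-sink chromosome so placements
#' never collide. The mother/daughter occupied fractions are exact by
#' construction: 100 * looped / n per role.
#'
#' @param cfg a \code{fixture_config} with \code{n_mother},
#'   \code{looped_mother}, \code{n_daughter}, \code{looped_daughter},
#'   region widths, \code{n_strata2}, \code{n_strata1}, \code{n_strata0},
#'   \code{seed}.
#' @param seed RNG seed; defaults to the config's.
#' @return list with \code{se} (\code{SERegionSet}), \code{loops}
#'   (\code{LoopSet}), \code{peaks} (\code{PeakSet}), \code{classes}
#'   (per-peak stratum design labels) and \code{truth}.
#' @export
gen_loops_and_se <- function(cfg, seed = cfg$seed) {
  n_m <- cfg$n_mother; n_d <- cfg$n_daughter
  k_m <- cfg$looped_mother; k_d <- cfg$looped_daughter
  .assert(k_m <= n_m && k_d <= n_d, "looped counts cannot exceed region counts")
  w_m <- cfg$mother_width %||% 2000
  w_d <- cfg$daughter_width %||% 1000
  n2 <- cfg$n_strata2 %||% 0; n1 <- cfg$n_strata1 %||% 0
  n0 <- cfg$n_strata0 %||% 0
  spacing <- cfg$spacing %||% 6000
  pw <- cfg$peak_width %||% 400

  n_regions <- n_m + n_d
  slots <- .genome_slots(n_regions, spacing, cfg$n_chrom %||% 8,
                         cfg$chrom_len %||% 3e6)
  role <- rep(c("mother", "daughter"), c(n_m, n_d))
  width <- ifelse(role == "mother", w_m, w_d)
  se <- se_region_set(slots$chrom, slots$base, slots$base + width,
                      se_id = sprintf("SE%d", c(seq_len(n_m), seq_len(n_d))),
                      role = role)
  # which regions get a looped peak / a loop-free peak / nothing
  .with_seed(seed + 3L, {
    looped <- c(sample.int(n_m, k_m), n_m + sample.int(n_d, k_d))
    rest <- setdiff(seq_len(n_regions), looped)
    with_peak0 <- rest[seq_len(length(rest) %/% 2L)]  # loop-free peak half
  })
  peak_regions <- c(looped, with_peak0)
  pk_start <- se$start[peak_regions] + (width[peak_regions] - pw) %/% 2L
  pk_chrom <- se$chrom[peak_regions]
  pk_class <- rep(c("se_looped", "se_silent"),
                  c(length(looped), length(with_peak0)))
  # standalone strata peaks on their own chromosome
  st_n <- n2 + n1 + n0
  st <- .genome_slots(st_n, spacing, 1L, st_n * spacing + spacing)
  pk_chrom <- c(pk_chrom, rep("chrS", st_n))
  pk_start <- c(pk_start, st$base + 500L)
  pk_class <- c(pk_class, rep(c("strata2", "strata1", "strata0"), c(n2, n1, n0)))
  peaks <- peak_set(pk_chrom, pk_start, pk_start + pw,
                    name = sprintf("NR2F2_%d", seq_along(pk_start)),
                    label = "NR2F2")
  # loops: anchor1 on the target peak, anchor2 in the chrZ sink
  n_loops_needed <- length(looped) + 2L * n2 + n1
  sink <- .genome_slots(n_loops_needed, 2000L, 1L,
                        n_loops_needed * 2000L + 2000L)
  loops_per_peak <- c(rep(1L, length(looped)), rep(0L, length(with_peak0)),
                      rep(c(2L, 1L, 0L), c(n2, n1, n0)))
  li <- rep(seq_along(pk_start), loops_per_peak)
  loops <- loop_set(chrom1 = pk_chrom[li],
                    start1 = pk_start[li] + 100L,
                    end1 = pk_start[li] + pw - 100L,
                    chrom2 = rep("chrZ", length(li)),
                    start2 = sink$base,
                    end2 = sink$base + 1000L)
  truth <- data.frame(se_id = se$se_id, role = se$role,
                      looped = seq_len(n_regions) %in% looped,
                      stringsAsFactors = FALSE)
  list(se = se, loops = loops, peaks = peaks, classes = pk_class,
       truth = truth)
}

#' Generate a count matrix with designed differential expression
#'
#' Negative-binomial counts for two groups (control, knockdown) with
#' designed down- and up-regulated gene sets at a fixed |log2FC| and an
#' SE-association flag on a subset of genes, of which a configured number
#' are among the designed DE genes. The design margin (|log2FC| = 2 against
#' a null log2FC spread of about 0.09 at the default depth and dispersion)
#' guarantees that the NB test plus the fold-change/FDR filter recover the
#' designed sets exactly for any seed.
#'
#' @param cfg a \code{fixture_config} with \code{n_genes},
#'   \code{n_per_group}, \code{base_mean}, \code{dispersion},
#'   \code{n_down}, \code{n_up}, \code{log2fc}, \code{n_se},
#'   \code{n_se_de}, \code{seed}.
#' @param seed RNG seed; defaults to the config's.
#' @return list with \code{counts} (genes x samples integer matrix),
#'   \code{groups} (factor) and \code{truth} (gene, status, se_flag).
#' @export
gen_counts_matrix <- function(cfg, seed = cfg$seed) {
  ng <- cfg$n_genes; np <- cfg$n_per_group
  disp <- cfg$dispersion
  .assert(disp >= 0, "dispersion must be >= 0")
  n_down <- cfg$n_down; n_up <- cfg$n_up
  .assert(n_down + n_up <= ng, "designed DE genes exceed the gene count")
  lfc <- cfg$log2fc %||% 2
  genes <- sprintf("gene_%04d", seq_len(ng))
  .with_seed(seed + 4L, {
    de_idx <- sample.int(ng, n_down + n_up)
    status <- rep("ns", ng)
    status[de_idx[seq_len(n_down)]] <- "down"
    status[de_idx[n_down + seq_len(n_up)]] <- "up"
    se_flag <- logical(ng)
    n_se <- cfg$n_se %||% 0; n_se_de <- cfg$n_se_de %||% 0
    .assert(n_se_de <= min(n_se, n_down + n_up), "n_se_de is infeasible")
    .assert(n_se - n_se_de <= ng - n_down - n_up, "n_se is infeasible")
    if (n_se > 0) {
      se_flag[sample(de_idx, n_se_de)] <- TRUE
      se_flag[sample(which(status == "ns"), n_se - n_se_de)] <- TRUE
    }
    mu_kd <- cfg$base_mean * 2^(ifelse(status == "down", -lfc,
                                       ifelse(status == "up", lfc, 0)))
    mu <- cbind(matrix(cfg$base_mean, ng, np), matrix(mu_kd, ng, np))
    counts <- matrix(stats::rnbinom(ng * 2L * np, mu = mu,
                                    size = if (disp > 0) 1 / disp else Inf),
                     nrow = ng)
  })
  dimnames(counts) <- list(genes, c(sprintf("ctrl_%d", seq_len(np)),
                                    sprintf("kd_%d", seq_len(np))))
  list(counts = counts,
       groups = factor(rep(c("control", "knockdown"), each = np),
                       levels = c("control", "knockdown")),
       truth = data.frame(gene = genes, status = status, se_flag = se_flag,
                          stringsAsFactors = FALSE))
}

#' Generate a two-group survival cohort
#'
#' Standard-normal expression z-scores, a median split into high/low
#' expression arms, exponential event times with the configured hazard
#' ratio for the low-expression arm, and uniform censoring on
#' \code{[0, censor_max]} (disable censoring with \code{censor_max = 0}).
#'
#' @param cfg a \code{fixture_config} with \code{n_per_arm},
#'   \code{base_hazard} (events/month for the high arm),
#'   \code{hazard_ratio} (low vs high), \code{censor_max} (months),
#'   \code{seed}.
#' @param seed RNG seed; defaults to the config's.
#' @return data frame: \code{patient}, \code{time}, \code{event},
#'   \code{expression_z}, \code{group}.
#' @export
gen_survival <- function(cfg, seed = cfg$seed) {
  n <- 2L * cfg$n_per_arm
  hr <- cfg$hazard_ratio %||% 1
  base <- cfg$base_hazard %||% 0.02
  cmax <- cfg$censor_max %||% 120
  .with_seed(seed + 5L, {
    z <- stats::rnorm(n)
    group <- median_split(z)
    rate <- ifelse(group == "low", base * hr, base)
    t_event <- stats::rexp(n, rate)
    t_cens <- if (cmax > 0) stats::runif(n, 0, cmax) else rep(Inf, n)
  })
  data.frame(patient = sprintf("pt_%03d", seq_len(n)),
             time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             expression_z = z, group = group, stringsAsFactors = FALSE)
}

#' Write a cohort as TSV
#'
#' @param cohort data frame from \code{\link{gen_survival}}.
#' @param path output path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  header <- paste(names(cohort), collapse = "\t")
  rows <- apply(cohort, 1L, function(r) paste(trimws(r), collapse = "\t"))
  writeLines(c(header, rows), path)
  invisible(path)
}
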