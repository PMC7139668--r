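# Count normalization, a simplified two-group negative-binomial exact-style
# differential test, fold-change/FDR filtering, SE-gene intersection, and a
# preranked enrichment score.

#' Log2 counts-per-million
#'
#' \code{log2((count + prior) / (libsize + 2*prior) * 1e6)}, with library
#' sizes taken as column totals.
#'
#' @param counts non-negative integer matrix (genes x samples).
#' @param prior prior count (> 0) stabilizing zeros.
#' @return numeric matrix of the same shape.
#' @export
log_cpm <- function(counts, prior = 0.5) {
  counts <- as.matrix(counts)
  .assert(prior > 0, "prior must be > 0")
  .assert(all(counts >= 0), "counts must be non-negative")
  lib <- colSums(counts)
  zero <- lib == 0
  if (any(zero)) {
    stop(sprintf("sample '%s' has zero library size",
                 (colnames(counts) %||% seq_len(ncol(counts)))[which(zero)[1L]]),
         call. = FALSE)
  }
  log2(sweep(sweep(counts, 2L, prior, "+"), 2L, lib + 2 * prior, "/") * 1e6)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median across genes of
#' the ratio of the sample's count to the gene's geometric mean, using only
#' genes expressed in every sample. Robust to composition shifts caused by
#' strongly asymmetric differential expression.
#'
#' @param counts non-negative integer matrix (genes x samples).
#' @return numeric vector of size factors (one per sample).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  lg <- rowMeans(log(counts))
  use <- is.finite(lg)
  .assert(any(use), "no gene is expressed in every sample")
  sf <- apply(counts[use, , drop = FALSE], 2L, function(cj) {
    exp(stats::median(log(cj) - lg[use]))
  })
  sf / exp(mean(log(sf)))
}

# Two-sided exact-style conditional test of group-sum counts. Under a
# common NB dispersion phi, the scaled group sums are NB with sizes
# r_i = n_i / phi and a shared success probability, so conditionally on the
# total T the first group's sum follows the negative hypergeometric
# (Dirichlet-multinomial) law; two-sided p sums all outcomes no more likely
# than the observed one (binom.test's minimum-likelihood rule). In the
# Poisson limit (phi ~ 0) this is the conditional binomial test.
.cond_nb_test <- function(kA, T, nA, nB, phi) {
  if (T == 0L) return(1)
  ks <- 0:T
  if (phi <= 1e-8) {
    logp <- stats::dbinom(ks, T, nA / (nA + nB), log = TRUE)
  } else {
    rA <- nA / phi; rB <- nB / phi
    logp <- lchoose(ks + rA - 1, ks) + lchoose(T - ks + rB - 1, T - ks)
    logp <- logp - max(logp)
    logp <- logp - log(sum(exp(logp)))
  }
  obs <- logp[kA + 1L]
  min(1, sum(exp(logp[logp <= obs + 1e-7])))
}

#' Simplified negative-binomial differential expression test
#'
#' A two-group exact-style test: counts are scaled by median-of-ratios size
#' factors, summed per group, and the first group's sum is tested against
#' its conditional null distribution given the total, under a common
#' negative-binomial dispersion estimated across genes by the method of
#' moments. Log2 fold changes are knockdown-vs-control differences of mean
#' log2 normalized counts (prior 0.5); p-values are BH-adjusted. Genes with
#' all-zero counts are reported with \code{log2fc = 0}, \code{p = 1} and
#' flagged. This is a deliberately simple stand-in for a full
#' empirical-Bayes GLM pipeline, adequate when effects are large relative
#' to the null spread.
#'
#' @param counts non-negative integer matrix (genes x samples) with gene
#'   rownames.
#' @param groups factor or character vector over samples with levels
#'   \code{control} and \code{knockdown} (first level = reference).
#' @param dispersion optional common NB dispersion; estimated when
#'   \code{NULL}.
#' @return data frame with columns \code{gene}, \code{log2fc}, \code{p},
#'   \code{fdr}, \code{all_zero}; the dispersion used is attached as
#'   attribute \code{"dispersion"}.
#' @export
de_test <- function(counts, groups, dispersion = NULL) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  .assert(nlevels(groups) == 2L, "exactly two groups are required")
  .assert(all(table(groups) >= 2L), "each group needs >= 2 samples")
  ref <- levels(groups)[1L]; alt <- levels(groups)[2L]
  iA <- which(groups == alt); iB <- which(groups == ref)  # A = knockdown
  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  log2fc <- rowMeans(log2(norm[, iA, drop = FALSE] + 0.5)) -
    rowMeans(log2(norm[, iB, drop = FALSE] + 0.5))
  if (is.null(dispersion)) {
    mom <- function(idx) {
      m <- rowMeans(norm[, idx, drop = FALSE])
      v <- apply(norm[, idx, drop = FALSE], 1L, stats::var)
      (v - m) / m^2
    }
    phis <- (mom(iA) + mom(iB)) / 2
    phis <- phis[is.finite(phis) & phis > 0]
    dispersion <- if (length(phis)) stats::median(phis) else 1e-8
  }
  .assert(dispersion >= 0, "dispersion must be >= 0")
  sumA <- round(rowSums(norm[, iA, drop = FALSE]))
  sumB <- round(rowSums(norm[, iB, drop = FALSE]))
  all_zero <- rowSums(counts) == 0
  p <- vapply(seq_len(nrow(counts)), function(g) {
    if (all_zero[g]) return(1)
    .cond_nb_test(sumA[g], sumA[g] + sumB[g], length(iA), length(iB),
                  dispersion)
  }, numeric(1L))
  log2fc[all_zero] <- 0
  res <- data.frame(gene = rownames(counts) %||% sprintf("gene_%d", seq_len(nrow(counts))),
                    log2fc = log2fc, p = p, fdr = bh_fdr(p),
                    all_zero = all_zero, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "dispersion") <- dispersion
  res
}

#' Filter differential-expression results on fold change and FDR
#'
#' A gene is called up when \code{log2fc >= log2(fc_min)} and
#' \code{fdr < fdr_max}, down when \code{log2fc <= -log2(fc_min)} and
#' \code{fdr < fdr_max}, otherwise not significant.
#'
#' @param results data frame from \code{\link{de_test}}.
#' @param fc_min minimum fold change (default 1.5).
#' @param fdr_max FDR cutoff (default 0.01).
#' @return list with character vectors \code{down} and \code{up}, and
#'   \code{results} carrying a \code{status} column in
#'   \code{\{up, down, ns\}}.
#' @export
de_filter <- function(results, fc_min = 1.5, fdr_max = 0.01) {
  .assert(fc_min >= 1, "fc_min must be >= 1")
  lfc <- log2(fc_min)
  status <- rep("ns", nrow(results))
  is_up <- results$log2fc >= lfc & results$fdr < fdr_max
  is_down <- results$log2fc <= -lfc & results$fdr < fdr_max
  status[is_up & !is_down] <- "up"
  status[is_down & !is_up] <- "down"   # log2fc == 0 at fc_min = 1 stays ns
  results$status <- status
  list(down = results$gene[status == "down"],
       up = results$gene[status == "up"],
       results = results)
}

#' Differential-expression count among SE-associated genes
#'
#' @param results data frame with \code{gene} and \code{status} columns
#'   (from \code{\link{de_filter}}).
#' @param se_genes character vector of genes flagged as associated with
#'   ERa-bound super-enhancers.
#' @return list with \code{n_se} (flagged genes present in the results) and
#'   \code{n_se_de} (those with status other than \code{ns}).
#' @export
se_gene_de_count <- function(results, se_genes) {
  .assert(!is.null(results$status), "results must carry a status column")
  flagged <- results$gene %in% se_genes
  list(n_se = sum(flagged), n_se_de = sum(flagged & results$status != "ns"))
}

#' Preranked enrichment score
#'
#' Classic weighted Kolmogorov-Smirnov running-sum statistic over a ranked
#' gene list: member genes increment the sum by their absolute score to the
#' power \code{p} (normalized), non-members decrement it uniformly; the
#' enrichment score is the signed maximum deviation, and the leading edge
#' is the member genes up to (or after, for negative scores) the extremum.
#'
#' @param scores named numeric vector of ranking scores, sorted in
#'   decreasing order (names = genes).
#' @param gene_set character vector, a proper non-empty subset of the
#'   ranked genes.
#' @param p weighting exponent (default 1; 0 gives the unweighted KS form).
#' @return list with \code{es}, \code{leading_edge}, \code{running}.
#' @export
preranked_es <- function(scores, gene_set, p = 1) {
  genes <- names(scores)
  .assert(!is.null(genes) && !anyDuplicated(genes), "scores must be uniquely named")
  .assert(!is.unsorted(rev(scores)), "scores must be sorted in decreasing order")
  inset <- genes %in% gene_set
  .assert(any(inset), "gene set is empty within the ranked universe")
  .assert(!all(inset), "gene set must be a proper subset of the universe")
  .assert(all(gene_set %in% genes), "gene set must be contained in the universe")
  w <- abs(scores)^p
  w[!inset] <- 0
  if (sum(w) == 0) w[inset] <- 1   # all-zero scores degenerate to p = 0
  step_hit <- w / sum(w)
  step_miss <- 1 / sum(!inset)
  running <- cumsum(ifelse(inset, step_hit, -step_miss))
  i <- which.max(abs(running))
  es <- running[i]
  leading <- if (es >= 0) genes[seq_len(i)][inset[seq_len(i)]]
  else genes[i:length(genes)][inset[i:length(genes)]]
  list(es = es, leading_edge = leading, running = running)
}

#' Read a gene x sample count table from TSV
#'
#' First column = gene ids, remaining columns = samples (header row).
#'
#' @param path path to the TSV file.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  .assert(all(m >= 0), "counts must be non-negative")
  m
}

#' Write a count matrix as TSV
#'
#' @param counts integer matrix with gene rownames.
#' @param path output path.
#' @export
write_counts_tsv <- function(counts, path) {
  header <- paste(c("gene", colnames(counts)), collapse = "\t")
  rows <- vapply(seq_len(nrow(counts)), function(i) {
    paste(c(rownames(counts)[i], counts[i, ]), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}
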