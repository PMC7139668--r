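# PWM construction, log-odds scanning on both strands, ZOOPS
# percent-of-target and hypergeometric known-motif enrichment over
# summit-centered ~100 bp sequences.

.BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix from base counts
#'
#' Converts a 4 x width base-count matrix into per-position probabilities
#' with a pseudocount, and log-odds scores in bits against a background
#' base composition. The default hit threshold is the smallest score whose
#' per-window false-positive probability under the background model is at
#' most \code{fpr}, computed by exact dynamic programming over the
#' discretized score distribution, and capped just below the maximum
#' achievable score so the consensus sequence always scores a hit.
#'
#' @param counts 4 x width numeric matrix (rows A, C, G, T) of observed
#'   base counts; every column must have at least one observation.
#' @param pseudocount added to every cell (default 0.25).
#' @param background length-4 base frequencies (A, C, G, T).
#' @param name motif identifier.
#' @param fpr target per-window, per-strand false-positive probability for
#'   the automatic threshold (default 1e-4).
#' @param threshold explicit hit threshold in bits, overriding \code{fpr}.
#' @return an object of class \code{PWM}.
#' @export
pwm_from_counts <- function(counts, pseudocount = 0.25,
                            background = rep(0.25, 4), name = "motif",
                            fpr = 1e-4, threshold = NULL) {
  counts <- as.matrix(counts)
  .assert(nrow(counts) == 4L, "counts must have 4 rows (A, C, G, T)")
  .assert(ncol(counts) >= 4L, "motif width must be >= 4")
  .assert(all(counts >= 0), "counts must be non-negative")
  .assert(all(colSums(counts) > 0), "every position needs >= 1 observation")
  .assert(pseudocount > 0, "pseudocount must be > 0")
  .assert(length(background) == 4L && all(background > 0) &&
            abs(sum(background) - 1) < 1e-6,
          "background must be 4 positive frequencies summing to 1")
  rownames(counts) <- .BASES
  probs <- sweep(counts + pseudocount, 2L, colSums(counts) + 4 * pseudocount, "/")
  logodds <- log2(probs / background)
  max_score <- sum(apply(logodds, 2L, max))
  if (is.null(threshold)) {
    threshold <- min(.pwm_threshold_fpr(logodds, background, fpr),
                     max_score - 1e-9)
  }
  .assert(is.finite(threshold), "threshold must be finite")
  structure(list(name = name, width = ncol(counts), probs = probs,
                 background = background, logodds = logodds,
                 threshold = threshold, max_score = max_score),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM '%s': width %d, consensus %s, threshold %.2f bits (max %.2f)\n",
              x$name, x$width, pwm_consensus(x), x$threshold, x$max_score))
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' @param pwm a \code{PWM}.
#' @return character string of per-position maximum-probability bases.
#' @export
pwm_consensus <- function(pwm) {
  paste(.BASES[apply(pwm$probs, 2L, which.max)], collapse = "")
}

# Exact score distribution under the iid background model, discretized to
# `step` bits. Returns the smallest grid score s with P(score >= s) <= fpr
# (Inf when even the maximum score is too likely; callers cap at max score).
.pwm_threshold_fpr <- function(logodds, background, fpr, step = 0.001) {
  keys <- round(logodds / step)
  probs <- 1; off <- 0
  for (j in seq_len(ncol(keys))) {
    kj <- keys[, j]
    newmin <- off + min(kj)
    newlen <- max(kj) - min(kj) + length(probs)
    acc <- numeric(newlen)
    for (b in 1:4) {
      at <- (off + kj[b] - newmin + 1L):(off + kj[b] - newmin + length(probs))
      acc[at] <- acc[at] + probs * background[b]
    }
    probs <- acc; off <- newmin
  }
  tail <- rev(cumsum(rev(probs)))
  hit <- which(tail <= fpr)
  if (!length(hit)) return(Inf)
  (off + hit[1L] - 1) * step
}

# Encode sequences as an integer matrix (A=1 C=2 G=3 T=4, N/other = NA).
# All sequences must share one length.
.encode_seq_matrix <- function(seqs) {
  seqs <- toupper(as.character(seqs))
  L <- unique(nchar(seqs))
  .assert(length(L) == 1L, "sequences must share one length for matrix scanning")
  codes <- match(strsplit(paste(seqs, collapse = ""), "")[[1L]], .BASES)
  matrix(codes, nrow = length(seqs), ncol = L, byrow = TRUE)
}

# Reverse-complement score matrix: scoring the + strand of the sequence
# with this matrix equals scoring the reverse complement window with the
# original PWM.
.rc_logodds <- function(logodds) logodds[4:1, rev(seq_len(ncol(logodds))), drop = FALSE]

# Which rows of an encoded sequence matrix contain >= 1 hit on either
# strand. Windows containing N (NA codes) are skipped.
.scan_any_hit <- function(pwm, codes) {
  n <- nrow(codes); L <- ncol(codes); w <- pwm$width
  hit <- logical(n)
  if (L < w || n == 0L) return(hit)
  lo <- pwm$logodds; rc <- .rc_logodds(lo)
  for (o in seq_len(L - w + 1L)) {
    sf <- numeric(n); sr <- numeric(n)
    for (j in seq_len(w)) {
      cj <- codes[, o + j - 1L]
      sf <- sf + lo[cbind(cj, j)]
      sr <- sr + rc[cbind(cj, j)]
    }
    hit <- hit | (!is.na(sf) & sf >= pwm$threshold) |
      (!is.na(sr) & sr >= pwm$threshold)
  }
  hit
}

#' Scan one sequence for motif hits on both strands
#'
#' Scores every window of the sequence with the PWM log-odds on the forward
#' strand and on the reverse complement, and reports all positions scoring
#' at or above the hit threshold. Windows containing N are skipped; a
#' sequence shorter than the motif yields an empty hit list.
#'
#' @param pwm a \code{PWM}.
#' @param seq a DNA string over A, C, G, T, N.
#' @param id sequence identifier carried into the result.
#' @return data frame with columns \code{seq_id}, \code{offset} (0-based),
#'   \code{strand}, \code{score} (bits).
#' @export
scan_sequence <- function(pwm, seq, id = "seq") {
  seq <- toupper(as.character(seq)[1L])
  codes <- match(strsplit(seq, "")[[1L]], .BASES)
  L <- length(codes); w <- pwm$width
  empty <- data.frame(seq_id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (L < w) return(empty)
  lo <- pwm$logodds; rc <- .rc_logodds(lo)
  n_win <- L - w + 1L
  sf <- numeric(n_win); sr <- numeric(n_win)
  for (j in seq_len(w)) {
    cj <- codes[seq_len(n_win) + j - 1L]
    sf <- sf + lo[cbind(cj, j)]
    sr <- sr + rc[cbind(cj, j)]
  }
  fh <- which(!is.na(sf) & sf >= pwm$threshold)
  rh <- which(!is.na(sr) & sr >= pwm$threshold)
  out <- data.frame(seq_id = rep(id, length(fh) + length(rh)),
                    offset = c(fh, rh) - 1L,
                    strand = rep(c("+", "-"), c(length(fh), length(rh))),
                    score = c(sf[fh], sr[rh]), stringsAsFactors = FALSE)
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' ZOOPS percent-of-target for a motif over a sequence set
#'
#' Counts the sequences containing at least one hit (zero-or-one occurrence
#' per sequence: hit multiplicity within a sequence does not matter) and
#' the resulting percentage, the "percent of target" reported by
#' known-motif enrichment tools.
#'
#' @param pwm a \code{PWM}.
#' @param seqs character vector or \code{Biostrings::DNAStringSet} of
#'   sequences (typically 100 bp summit-centered windows).
#' @return list with \code{k} (hit sequences), \code{n}, \code{percent}.
#' @export
percent_of_targets <- function(pwm, seqs) {
  seqs <- as.character(seqs)
  .assert(length(seqs) >= 1L, "need at least one sequence")
  if (length(unique(nchar(seqs))) == 1L) {
    hit <- .scan_any_hit(pwm, .encode_seq_matrix(seqs))
  } else {
    hit <- vapply(seq_along(seqs), function(i) {
      nrow(scan_sequence(pwm, seqs[i], id = as.character(i))) > 0L
    }, logical(1L))
  }
  k <- sum(hit)
  list(k = k, n = length(seqs), percent = 100 * k / length(seqs), hit = hit)
}

#' Hypergeometric known-motif enrichment test
#'
#' ZOOPS hit counts in target and background sequence sets are compared
#' with an upper hypergeometric tail: the probability of drawing at least
#' \code{k_target} hit-sequences in \code{n_target} draws from the pooled
#' urn of all sequences.
#'
#' @param pwm a \code{PWM}.
#' @param target_seqs,background_seqs sequence sets (character or
#'   \code{DNAStringSet}); a background smaller than the target triggers a
#'   warning but the test proceeds.
#' @return one-row data frame: \code{motif}, \code{n_target},
#'   \code{k_target}, \code{n_background}, \code{k_background},
#'   \code{percent_of_target}, \code{p}.
#' @export
motif_enrichment_test <- function(pwm, target_seqs, background_seqs) {
  t <- percent_of_targets(pwm, target_seqs)
  b <- percent_of_targets(pwm, background_seqs)
  if (b$n < t$n) warning("background set is smaller than the target set")
  p <- hypergeom_tail(t$k, t$n + b$n, t$k + b$k, t$n)
  data.frame(motif = pwm$name, n_target = t$n, k_target = t$k,
             n_background = b$n, k_background = b$k,
             percent_of_target = t$percent, p = p, stringsAsFactors = FALSE)
}

#' Read a JASPAR-style motif count-matrix library
#'
#' Parses a plain-text library of count matrices in the JASPAR layout
#' (\code{>NAME} header, then four lines \code{A [ n n ... ]} through
#' \code{T [ ... ]}). The packaged default library carries count matrices
#' constructed from the canonical published consensus sequences of the
#' estrogen-receptor co-factor motifs (ERE, DR1, FOXA1, GATA3, AP-1,
#' AP2-gamma, CTCF, NR half-site); it is a synthetic stand-in, not a
#' database export.
#'
#' @param path library file; default the packaged synthetic library.
#' @return named list of 4 x width count matrices.
#' @export
read_motif_library <- function(path = system.file("extdata",
                                                  "motif_library_synthetic.txt",
                                                  package = "cistroflow")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  heads <- grep("^>", lines)
  .assert(length(heads) > 0, "no motif headers in %s", path)
  out <- list()
  for (i in seq_along(heads)) {
    name <- sub("^>\\s*", "", lines[heads[i]])
    block <- lines[(heads[i] + 1L):(heads[i] + 4L)]
    rows <- lapply(block, function(l) {
      nums <- regmatches(l, gregexpr("[0-9.]+", l))[[1L]]
      as.numeric(nums)
    })
    .assert(length(unique(lengths(rows))) == 1L,
            "motif %s: ragged count matrix", name)
    m <- do.call(rbind, rows)
    rownames(m) <- .BASES
    out[[name]] <- m
  }
  out
}

#' Load the motif library as ready-to-scan PWMs
#'
#' @inheritParams read_motif_library
#' @inheritParams pwm_from_counts
#' @return named list of \code{PWM} objects.
#' @export
load_motif_pwms <- function(path = system.file("extdata",
                                               "motif_library_synthetic.txt",
                                               package = "cistroflow"),
                            pseudocount = 0.25, background = rep(0.25, 4),
                            fpr = 1e-4) {
  counts <- read_motif_library(path)
  lapply(stats::setNames(names(counts), names(counts)), function(nm) {
    pwm_from_counts(counts[[nm]], pseudocount = pseudocount,
                    background = background, name = nm, fpr = fpr)
  })
}

#' Read sequences from a FASTA file
#'
#' @param path path to an uncompressed FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
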