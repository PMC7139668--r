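# Brute-force reference implementations and random-instance generators used
# by the oracle-equivalence tests. These deliberately use naive all-pairs /
# per-base algorithms, independent of the package's interval engine.

bp_overlap <- function(s1, e1, s2, e2) max(0L, min(e1, e2) - max(s1, s2))

# All-pairs occupancy partition: shared iff >= min_overlap shared bp with
# any peak of the other set on the same chromosome.
bf_partition <- function(a, b, min_overlap = 1L) {
  shared_a <- vapply(seq_len(nrow(a)), function(i) {
    any(vapply(seq_len(nrow(b)), function(j) {
      a$chrom[i] == b$chrom[j] &&
        bp_overlap(a$start[i], a$end[i], b$start[j], b$end[j]) >= min_overlap
    }, logical(1)))
  }, logical(1))
  shared_b <- vapply(seq_len(nrow(b)), function(j) {
    any(vapply(seq_len(nrow(a)), function(i) {
      a$chrom[i] == b$chrom[j] &&
        bp_overlap(a$start[i], a$end[i], b$start[j], b$end[j]) >= min_overlap
    }, logical(1)))
  }, logical(1))
  list(shared_a = shared_a, shared_b = shared_b)
}

# All-pairs loop counting: one count per loop whose anchor1 OR anchor2
# overlaps the peak (a loop hit on both anchors counts once).
bf_loop_counts <- function(peaks, loops) {
  vapply(seq_len(nrow(peaks)), function(i) {
    sum(vapply(seq_len(nrow(loops)), function(l) {
      hit1 <- peaks$chrom[i] == loops$chrom1[l] &&
        bp_overlap(peaks$start[i], peaks$end[i],
                   loops$start1[l], loops$end1[l]) >= 1L
      hit2 <- peaks$chrom[i] == loops$chrom2[l] &&
        bp_overlap(peaks$start[i], peaks$end[i],
                   loops$start2[l], loops$end2[l]) >= 1L
      hit1 || hit2
    }, logical(1)))
  }, integer(1))
}

# Naive per-bin fragment counting: test every (fragment, bin) pair.
bf_pileup <- function(frags, window, bin) {
  fr <- frags$fragments
  if (!is.null(window$chrom)) fr <- fr[fr$chrom == window$chrom, , drop = FALSE]
  width <- window$end - window$start
  nb <- width %/% bin
  vapply(seq_len(nb), function(k) {
    bs <- window$start + (k - 1L) * bin; be <- bs + bin
    sum(vapply(seq_len(nrow(fr)), function(i) {
      bp_overlap(fr$start[i], fr$end[i], bs, be) >= 1L
    }, logical(1)))
  }, integer(1))
}

# Fragments overlapping the inclusive summit window, counted one by one.
bf_window_count <- function(frags, chrom, start, end) {
  fr <- frags$fragments
  sum(fr$chrom == chrom & fr$start < end & fr$end > start)
}

# Exhaustive nearest-TSS scan with the documented tie rules.
bf_nearest <- function(peaks, tss) {
  pos <- as.integer(tss$start)
  if (!is.null(tss$strand) && !is.null(tss$end)) {
    neg <- tss$strand == "-"
    pos[neg] <- as.integer(tss$end[neg]) - 1L
  }
  vapply(seq_len(nrow(peaks)), function(i) {
    ti <- which(tss$chrom == peaks$chrom[i])
    if (!length(ti)) return(NA_character_)
    d <- abs(peaks$summit[i] - pos[ti])
    cand <- ti[d == min(d)]
    cand <- cand[pos[cand] == min(pos[cand])]
    sort(tss$gene_id[cand])[1L]
  }, character(1))
}

rand_peaks <- function(n, seed, n_chrom = 2L, glen = 1e5, max_w = 2000L,
                       label = "rand") {
  set.seed(seed)
  start <- sample.int(glen - max_w, n, replace = TRUE)
  w <- sample.int(max_w - 1L, n, replace = TRUE) + 1L
  peak_set(chrom = sprintf("chr%d", sample.int(n_chrom, n, replace = TRUE)),
           start = start, end = start + w, label = label)
}

rand_frags <- function(n, seed, n_chrom = 1L, glen = 1e4, max_w = 300L) {
  set.seed(seed)
  start <- sample.int(glen, n, replace = TRUE)
  w <- sample.int(max_w - 1L, n, replace = TRUE) + 1L
  fragment_set(chrom = sprintf("chr%d", sample.int(n_chrom, n, replace = TRUE)),
               start = start, end = start + w)
}

rand_loops <- function(n, seed, n_chrom = 2L, glen = 1e5, anchor_w = 1000L) {
  set.seed(seed)
  s1 <- sample.int(glen - anchor_w, n, replace = TRUE)
  s2 <- sample.int(glen - anchor_w, n, replace = TRUE)
  loop_set(chrom1 = sprintf("chr%d", sample.int(n_chrom, n, replace = TRUE)),
           start1 = s1, end1 = s1 + anchor_w,
           chrom2 = sprintf("chr%d", sample.int(n_chrom, n, replace = TRUE)),
           start2 = s2, end2 = s2 + anchor_w)
}

write_tmp <- function(lines, ext = ".bed") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
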