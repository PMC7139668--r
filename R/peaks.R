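# Genomic interval types, BED I/O, overlap partitioning, summit windows and
# nearest-TSS annotation. Coordinates follow the BED convention throughout:
# 0-based, half-open [start, end).

#' Construct a PeakSet
#'
#' A \code{PeakSet} is a data frame of ChIP-seq peaks (one cistrome) with
#' columns \code{chrom}, \code{start}, \code{end}, \code{name}, \code{score},
#' \code{strand}, \code{summit} and a factor label attribute (e.g. "ERalpha",
#' "NR2F2"). Coordinates are 0-based half-open; the summit, when present,
#' is an absolute base position inside \code{[start, end)}.
#'
#' @param chrom chromosome names (non-empty strings).
#' @param start,end 0-based half-open coordinates; \code{end > start >= 0}.
#' @param name unique peak identifiers; autogenerated when \code{NULL}.
#' @param score non-negative numeric scores (default 0).
#' @param strand one of \code{"+"}, \code{"-"}, \code{"."}.
#' @param summit absolute summit positions, or \code{NA}; defaults to the
#'   interval midpoint \code{floor((start + end)/2)}.
#' @param label name of the factor whose cistrome this is.
#' @return an object of class \code{PeakSet} (a data frame).
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = 0, strand = ".",
                     summit = NULL, label = "peaks") {
  n <- length(chrom)
  start <- as.integer(start); end <- as.integer(end)
  .assert(all(nzchar(chrom)), "chrom names must be non-empty")
  .assert(all(start >= 0L), "start must be >= 0")
  .assert(all(end > start), "end must be > start for every peak")
  if (is.null(name)) name <- sprintf("peak_%d", seq_len(n))
  .assert(!anyDuplicated(name), "peak names must be unique within a set")
  if (is.null(summit)) summit <- (start + end) %/% 2L
  summit <- as.integer(summit)
  ok <- is.na(summit) | (summit >= start & summit < end)
  .assert(all(ok), "summit must lie in [start, end)")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = as.character(name),
                   score = rep_len(as.numeric(score), n),
                   strand = rep_len(as.character(strand), n),
                   summit = summit, stringsAsFactors = FALSE)
  structure(df, class = c("PeakSet", "data.frame"), label = label)
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet '%s': %d peaks on %d chromosome(s)\n",
              attr(x, "label") %||% "peaks", nrow(x),
              length(unique(x$chrom))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' @return the label attribute of a PeakSet or FragmentSet.
#' @rdname peak_set
#' @param x a PeakSet.
#' @export
set_label <- function(x) attr(x, "label") %||% "peaks"

.subset_peaks <- function(ps, idx) {
  out <- as.data.frame(ps)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("PeakSet", "data.frame"), label = attr(ps, "label"))
}

# PeakSet (0-based half-open) -> GRanges (1-based closed)
.peaks_gr <- function(ps) {
  GenomicRanges::GRanges(ps$chrom,
                         IRanges::IRanges(start = ps$start + 1L, end = ps$end))
}

.intervals_gr <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end))
}

#' Read peak calls from a BED or narrowPeak file
#'
#' Reads BED3+/BED6 (\code{dialect = "bed3plus"}) or 10-column ENCODE
#' narrowPeak (\code{dialect = "narrowpeak"}) into a \code{\link{peak_set}}.
#' For narrowPeak records the summit is \code{start + offset} (column 10)
#' when the offset is non-negative, otherwise the interval midpoint; BED
#' records always get midpoint summits. Malformed coordinates raise an error
#' naming the offending line.
#'
#' @param path path to a tab-separated peak file.
#' @param dialect \code{"bed3plus"} or \code{"narrowpeak"}.
#' @param exclude optional path to a BED3 exclusion (artifact/blacklist)
#'   file; peaks overlapping any excluded interval by >= 1 bp are dropped
#'   before the set is returned.
#' @param label factor label for the resulting set.
#' @return a \code{PeakSet}.
#' @export
read_bed <- function(path, dialect = c("bed3plus", "narrowpeak"),
                     exclude = NULL, label = NULL) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) stop("unknown BED dialect", call. = FALSE))
  min_cols <- if (dialect == "narrowpeak") 10L else 3L
  tab <- .read_tab_lines(path, min_cols)
  n <- length(tab$fields)
  chrom <- .tab_col(tab, 1L)
  start <- .tab_int(tab, 2L, path, "start")
  end <- .tab_int(tab, 3L, path, "end")
  .check_coords(start, end, tab, path)
  nf <- min(lengths(tab$fields))
  name <- if (nf >= 4L) .tab_col(tab, 4L) else sprintf("peak_%d", seq_len(n))
  score <- if (nf >= 5L) suppressWarnings(as.numeric(.tab_col(tab, 5L))) else rep(0, n)
  score[is.na(score)] <- 0
  strand <- if (nf >= 6L) .tab_col(tab, 6L) else rep(".", n)
  strand[!strand %in% c("+", "-", ".")] <- "."
  summit <- (start + end) %/% 2L
  if (dialect == "narrowpeak") {
    offset <- .tab_int(tab, 10L, path, "summit offset")
    use <- offset >= 0L
    summit[use] <- start[use] + offset[use]
    bad <- use & (summit >= end)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("%s: line %d: summit offset %d falls outside the peak",
                   path, tab$lineno[i], offset[i]), call. = FALSE)
    }
  }
  ps <- peak_set(chrom, start, end, name = name, score = score,
                 strand = strand, summit = summit,
                 label = label %||% sub("\\.[^.]*$", "", basename(path)))
  if (!is.null(exclude)) ps <- subtract_exclusion(ps, exclude)
  ps
}

#' Remove peaks overlapping an exclusion list
#'
#' Drops every peak that overlaps (>= 1 bp) an interval of a BED3 exclusion
#' file, the standard artifact/blacklist filtering step applied before any
#' occupancy comparison.
#'
#' @param peaks a \code{PeakSet}.
#' @param exclude path to a BED3 file of excluded regions.
#' @return the filtered \code{PeakSet}.
#' @export
subtract_exclusion <- function(peaks, exclude) {
  tab <- .read_tab_lines(exclude, 3L)
  chrom <- .tab_col(tab, 1L)
  start <- .tab_int(tab, 2L, exclude, "start")
  end <- .tab_int(tab, 3L, exclude, "end")
  .check_coords(start, end, tab, exclude)
  hits <- .fo(.peaks_gr(peaks), .intervals_gr(chrom, start, end))
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop)) .subset_peaks(peaks, -drop) else peaks
}

#' Write a PeakSet as BED6
#'
#' @param peaks a \code{PeakSet}.
#' @param path output path.
#' @export
write_bed <- function(peaks, path) {
  df <- as.data.frame(peaks)
  lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s", df$chrom, df$start, df$end,
                   df$name, df$score, df$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Partition two cistromes into shared and factor-specific peaks
#'
#' Occupancy-mode overlap partitioning: a peak of set A is classified
#' "shared" if and only if it overlaps at least one peak of set B by at
#' least \code{min_overlap} bp (half-open arithmetic), and symmetrically for
#' B. A shared peak overlapping several partners is counted once, giving the
#' fraction-of-peaks semantics of a binding-site Venn diagram.
#'
#' @param a,b \code{PeakSet}s on the same genome.
#' @param min_overlap minimum shared base pairs (>= 1) to call an overlap.
#' @return an \code{OccupancyPartition}: list with \code{PeakSet} elements
#'   \code{shared_a}, \code{only_a}, \code{shared_b}, \code{only_b} and the
#'   input labels.
#' @export
overlap_partition <- function(a, b, min_overlap = 1L) {
  .assert(min_overlap >= 1, "min_overlap must be >= 1")
  if (nrow(a) == 0L || nrow(b) == 0L) {
    shared_idx_a <- integer(0); shared_idx_b <- integer(0)
  } else {
    hits <- .fo(.peaks_gr(a), .peaks_gr(b), min_overlap)
    shared_idx_a <- sort(unique(S4Vectors::queryHits(hits)))
    shared_idx_b <- sort(unique(S4Vectors::subjectHits(hits)))
  }
  only_idx_a <- setdiff(seq_len(nrow(a)), shared_idx_a)
  only_idx_b <- setdiff(seq_len(nrow(b)), shared_idx_b)
  structure(list(shared_a = .subset_peaks(a, shared_idx_a),
                 only_a = .subset_peaks(a, only_idx_a),
                 shared_b = .subset_peaks(b, shared_idx_b),
                 only_b = .subset_peaks(b, only_idx_b),
                 label_a = set_label(a), label_b = set_label(b),
                 min_overlap = as.integer(min_overlap)),
            class = "OccupancyPartition")
}

#' Shared fraction of an occupancy partition
#'
#' @param part an \code{OccupancyPartition}.
#' @param set \code{"a"} or \code{"b"}.
#' @return the percentage (0-100) of that set's peaks classified shared.
#' @export
shared_fraction <- function(part, set = c("a", "b")) {
  set <- match.arg(set)
  sh <- nrow(part[[paste0("shared_", set)]])
  tot <- sh + nrow(part[[paste0("only_", set)]])
  if (tot == 0L) return(NA_real_)
  100 * sh / tot
}

#' @export
print.OccupancyPartition <- function(x, ...) {
  na <- nrow(x$shared_a) + nrow(x$only_a)
  nb <- nrow(x$shared_b) + nrow(x$only_b)
  cat(sprintf("Occupancy partition (min_overlap = %d bp)\n", x$min_overlap))
  cat(sprintf("  %s: %d peaks, %d shared (%.2f%%)\n", x$label_a, na,
              nrow(x$shared_a), shared_fraction(x, "a")))
  cat(sprintf("  %s: %d peaks, %d shared (%.2f%%)\n", x$label_b, nb,
              nrow(x$shared_b), shared_fraction(x, "b")))
  invisible(x)
}

#' Summit-centered window
#'
#' The inclusive flanking window \code{[summit - flank, summit + flank + 1)},
#' left-clipped at zero: width \code{2*flank + 1} bp when unclipped (101 bp
#' for the RPKM flank of 50).
#'
#' @param summit absolute summit position(s), 0-based.
#' @param flank flanking distance in bp (>= 0).
#' @return data frame with columns \code{start}, \code{end}.
#' @export
summit_window <- function(summit, flank) {
  .assert(all(flank >= 0), "flank must be >= 0")
  summit <- as.integer(summit)
  data.frame(start = pmax(0L, summit - as.integer(flank)),
             end = summit + as.integer(flank) + 1L)
}

#' Annotate peaks with their nearest TSS
#'
#' Assigns each peak the gene whose transcription start site minimizes the
#' absolute distance to the peak summit. Ties are broken by the smaller
#' genomic coordinate, then by lexicographic gene id. The TSS of a
#' minus-strand record is its \code{end - 1} position, otherwise
#' \code{start}. Peaks on chromosomes without any TSS are assigned
#' \code{NA} with a warning.
#'
#' @param peaks a \code{PeakSet} with summits.
#' @param tss data frame with columns \code{chrom}, \code{start}, optionally
#'   \code{end} and \code{strand}, and \code{gene_id}.
#' @return data frame with columns \code{name}, \code{gene_id},
#'   \code{distance}.
#' @export
nearest_tss_annotate <- function(peaks, tss) {
  .assert(nrow(tss) > 0, "TSS annotation must be non-empty")
  pos <- as.integer(tss$start)
  if (!is.null(tss$strand) && !is.null(tss$end)) {
    neg <- tss$strand == "-"
    pos[neg] <- as.integer(tss$end[neg]) - 1L
  }
  out_gene <- rep(NA_character_, nrow(peaks))
  out_dist <- rep(NA_integer_, nrow(peaks))
  for (chr in unique(peaks$chrom)) {
    pk <- which(peaks$chrom == chr)
    ti <- which(tss$chrom == chr)
    if (!length(ti)) next
    ord <- ti[order(pos[ti], tss$gene_id[ti])]
    ord <- ord[!duplicated(pos[ord])]   # lexicographic-smallest gene per position
    p <- pos[ord]; g <- tss$gene_id[ord]
    s <- peaks$summit[pk]
    lo <- findInterval(s, p)            # index of rightmost p <= s (0 if none)
    hi <- pmin(lo + 1L, length(p))
    lo <- pmax(lo, 1L)
    dl <- abs(s - p[lo]); dh <- abs(s - p[hi])
    use_hi <- dh < dl                   # strict: ties go to the smaller coordinate
    pick <- ifelse(use_hi, hi, lo)
    out_gene[pk] <- g[pick]
    out_dist[pk] <- as.integer(abs(s - p[pick]))
  }
  if (anyNA(out_gene)) {
    warning(sprintf("%d peak(s) on chromosomes without a TSS assigned NA",
                    sum(is.na(out_gene))))
  }
  data.frame(name = peaks$name, gene_id = out_gene, distance = out_dist,
             stringsAsFactors = FALSE)
}
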