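# Fragment pileup, summit-centered tag-density profiles and heatmap
# matrices, and summit +/- 50 bp RPKM quantification.
#
# Windowing conventions: density/heatmap windows are half-open
# [summit - flank, summit + flank) of width 2*flank so that the default bins
# (10 bp for profiles, 25 bp for heatmaps) divide the window exactly; the
# RPKM window is the inclusive summit window [summit - 50, summit + 51) of
# 101 bp (see summit_window()).

#' Construct a FragmentSet
#'
#' Aligned, pre-extended sequencing fragments for one track. Fragments are
#' used as provided (no strand shift or extension model); the library size
#' is the total fragment count and is the denominator of all normalized
#' quantities.
#'
#' @param chrom,start,end fragment intervals (0-based half-open).
#' @param label track name.
#' @return an object of class \code{FragmentSet}.
#' @export
fragment_set <- function(chrom, start, end, label = "fragments") {
  start <- as.integer(start); end <- as.integer(end)
  .assert(all(start >= 0L), "fragment start must be >= 0")
  .assert(all(end > start), "fragment end must be > start")
  structure(list(fragments = data.frame(chrom = as.character(chrom),
                                        start = start, end = end,
                                        stringsAsFactors = FALSE),
                 library_size = length(start), label = label),
            class = "FragmentSet")
}

#' @export
print.FragmentSet <- function(x, ...) {
  cat(sprintf("FragmentSet '%s': %d fragments\n", x$label, x$library_size))
  invisible(x)
}

#' Read fragments from a BED3+ file
#'
#' @param path path to a BED file of fragment intervals.
#' @param label track name (defaults to the file stem).
#' @return a \code{FragmentSet}.
#' @export
read_fragments <- function(path, label = NULL) {
  tab <- .read_tab_lines(path, 3L)
  chrom <- .tab_col(tab, 1L)
  start <- .tab_int(tab, 2L, path, "start")
  end <- .tab_int(tab, 3L, path, "end")
  .check_coords(start, end, tab, path)
  fragment_set(chrom, start, end,
               label = label %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Binned fragment pileup over a window
#'
#' Counts, for each bin of the window, the fragments overlapping that bin
#' (half-open arithmetic); a fragment spanning several bins contributes one
#' count to each.
#'
#' @param frags a \code{FragmentSet}.
#' @param window list or one-row data frame with \code{start}, \code{end}
#'   and optionally \code{chrom}.
#' @param bin bin width in bp; must divide the window width.
#' @return integer vector of per-bin fragment counts.
#' @export
pileup_coverage <- function(frags, window, bin = 1L) {
  ws <- as.integer(window$start); we <- as.integer(window$end)
  width <- we - ws
  .assert(width > 0, "window must have positive width")
  .assert(bin >= 1, "bin must be >= 1")
  if (width %% bin != 0) {
    stop(sprintf("bin width %d does not divide window width %d", bin, width),
         call. = FALSE)
  }
  fr <- frags$fragments
  if (!is.null(window$chrom)) fr <- fr[fr$chrom == window$chrom, , drop = FALSE]
  ov <- fr$start < we & fr$end > ws
  nb <- width %/% bin
  if (!any(ov)) return(integer(nb))
  b0 <- (pmax(fr$start[ov], ws) - ws) %/% bin
  b1 <- (pmin(fr$end[ov], we) - ws - 1L) %/% bin
  delta <- tabulate(b0 + 1L, nbins = nb + 1L) -
    tabulate(b1 + 2L, nbins = nb + 1L)
  as.integer(cumsum(delta)[seq_len(nb)])
}

# Per-peak binned fragment counts around summits. Returns list(counts =
# n_kept x n_bin matrix with peak-name rownames, kept = kept row indices).
# Windows are [summit - flank, summit + flank); peaks whose window would be
# left-clipped below 0 are dropped with a warning.
.summit_bin_counts <- function(peaks, frags, flank, bin) {
  .assert(nrow(peaks) > 0, "no peaks to profile")
  .assert(!anyNA(peaks$summit), "all peaks must carry a summit")
  .assert(flank >= 1, "flank must be >= 1")
  if ((2L * flank) %% bin != 0) {
    stop(sprintf("bin width %d does not divide window width %d", bin, 2L * flank),
         call. = FALSE)
  }
  keep <- peaks$summit - flank >= 0L
  if (!all(keep)) {
    warning(sprintf("%d peak(s) with left-clipped windows dropped from profiling",
                    sum(!keep)))
  }
  kept <- which(keep)
  .assert(length(kept) > 0, "no peaks to profile")
  ws <- peaks$summit[kept] - as.integer(flank)
  we <- peaks$summit[kept] + as.integer(flank)
  nb <- (2L * flank) %/% bin
  npk <- length(kept)
  wgr <- .intervals_gr(peaks$chrom[kept], ws, we)
  fr <- frags$fragments
  fgr <- .intervals_gr(fr$chrom, fr$start, fr$end)
  hits <- .fo(fgr, wgr)
  qi <- S4Vectors::queryHits(hits); sj <- S4Vectors::subjectHits(hits)
  counts <- matrix(0, nrow = npk, ncol = nb,
                   dimnames = list(peaks$name[kept], NULL))
  if (length(qi)) {
    b0 <- (pmax(fr$start[qi], ws[sj]) - ws[sj]) %/% bin
    b1 <- (pmin(fr$end[qi], we[sj]) - ws[sj] - 1L) %/% bin
    nslots <- npk * (nb + 1L)
    delta <- tabulate(sj + b0 * npk, nbins = nslots) -
      tabulate(sj + (b1 + 1L) * npk, nbins = nslots)
    D <- matrix(delta, nrow = npk, ncol = nb + 1L)
    counts <- t(apply(D, 1L, cumsum))[, seq_len(nb), drop = FALSE]
    rownames(counts) <- peaks$name[kept]
  }
  list(counts = counts, kept = kept)
}

#' Summit-centered tag-density profile
#'
#' Per-peak binned fragment counts in the window around each summit,
#' averaged over peaks and normalized to tags per 1e7 sequenced fragments
#' (the HOMER-like fixed-library normalization). Default flanks are 500 bp
#' for histogram-style profiles and 1000 bp for heatmaps.
#'
#' @param peaks a \code{PeakSet} with summits.
#' @param frags a \code{FragmentSet}.
#' @param flank half-window in bp (window width \code{2*flank}).
#' @param bin bin width in bp; must divide \code{2*flank}.
#' @param norm_tags library size the profile is normalized to (default 1e7).
#' @return a \code{DensityProfile}: list with \code{offsets} (bin start
#'   offsets relative to the summit), \code{values}, \code{n_peaks},
#'   \code{flank}, \code{bin}, \code{label}.
#' @export
tag_density_profile <- function(peaks, frags, flank = 500L, bin = 10L,
                                norm_tags = 1e7) {
  .assert(frags$library_size > 0, "fragment library is empty")
  bc <- .summit_bin_counts(peaks, frags, flank, bin)
  values <- colMeans(bc$counts) * norm_tags / frags$library_size
  structure(list(offsets = seq(-flank, flank - bin, by = bin),
                 values = as.numeric(values),
                 n_peaks = nrow(bc$counts), flank = as.integer(flank),
                 bin = as.integer(bin), label = frags$label),
            class = "DensityProfile")
}

#' @export
print.DensityProfile <- function(x, ...) {
  cat(sprintf("DensityProfile '%s': %d peaks, flank %d bp, bin %d bp, peak value %.3f\n",
              x$label, x$n_peaks, x$flank, x$bin, max(x$values)))
  invisible(x)
}

#' Per-peak signal heatmap matrix
#'
#' The per-peak, per-bin normalized tag counts underlying a signal heatmap
#' (no averaging over peaks). Rows are sorted by decreasing row sum, ties
#' broken by peak name, so the ordering is deterministic.
#'
#' @inheritParams tag_density_profile
#' @return numeric matrix (peaks x bins) with peak-name rownames.
#' @export
heatmap_matrix <- function(peaks, frags, flank = 1000L, bin = 25L,
                           norm_tags = 1e7) {
  .assert(frags$library_size > 0, "fragment library is empty")
  bc <- .summit_bin_counts(peaks, frags, flank, bin)
  m <- bc$counts * norm_tags / frags$library_size
  ord <- order(-rowSums(m), rownames(m))
  m[ord, , drop = FALSE]
}

#' Summit +/- 50 bp RPKM
#'
#' Reads per kilobase per million mapped reads computed on the fixed
#' 101 bp inclusive summit window: \code{count / (0.101 * library_size/1e6)},
#' where \code{count} is the number of fragments overlapping the window.
#' The window width is fixed, so RPKM is invariant to peak width.
#'
#' @param peaks a \code{PeakSet} with summits.
#' @param frags a \code{FragmentSet}.
#' @param flank half-window in bp (default 50, giving the 101 bp window).
#' @return data frame with columns \code{name}, \code{count}, \code{rpkm}.
#' @export
rpkm_summit <- function(peaks, frags, flank = 50L) {
  .assert(frags$library_size > 0, "fragment library size must be > 0")
  .assert(nrow(peaks) > 0, "no peaks to quantify")
  .assert(!anyNA(peaks$summit), "all peaks must carry a summit")
  win <- summit_window(peaks$summit, flank)
  wgr <- .intervals_gr(peaks$chrom, win$start, win$end)
  fr <- frags$fragments
  fgr <- .intervals_gr(fr$chrom, fr$start, fr$end)
  hits <- .fo(wgr, fgr)
  count <- tabulate(S4Vectors::queryHits(hits), nbins = nrow(peaks))
  window_kb <- (2L * flank + 1L) / 1000
  rpkm <- count / (window_kb * frags$library_size / 1e6)
  data.frame(name = peaks$name, count = count, rpkm = rpkm,
             stringsAsFactors = FALSE)
}

#' Write a density profile or heatmap matrix as TSV
#'
#' @param x a \code{DensityProfile} or a matrix from
#'   \code{\link{heatmap_matrix}}.
#' @param path output path.
#' @export
write_profile_tsv <- function(x, path) {
  if (inherits(x, "DensityProfile")) {
    writeLines(c(paste(c("offset", "density"), collapse = "\t"),
                 sprintf("%d\t%.6f", x$offsets, x$values)), path)
  } else {
    header <- paste(c("name", colnames(x) %||% seq_len(ncol(x))), collapse = "\t")
    rows <- vapply(seq_len(nrow(x)), function(i) {
      paste(c(rownames(x)[i], sprintf("%.6f", x[i, ])), collapse = "\t")
    }, character(1L))
    writeLines(c(header, rows), path)
  }
  invisible(path)
}
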