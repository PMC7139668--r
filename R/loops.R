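# ChIA-PET loop parsing (BEDPE), per-peak loop-count stratification
# (>=2 / 1 / 0 interactions) and super-enhancer mother/daughter occupancy
# fractions.

.STRATA <- c("0", "1", ">=2")

#' Construct a loop collection
#'
#' Chromatin loops as paired anchor intervals. Anchors are canonicalized so
#' anchor1 precedes anchor2 in genome order (chromosome, then start).
#'
#' @param chrom1,start1,end1,chrom2,start2,end2 anchor intervals (0-based
#'   half-open).
#' @param name loop identifiers; autogenerated when \code{NULL}.
#' @param support optional PET support counts.
#' @return data frame of class \code{LoopSet}.
#' @export
loop_set <- function(chrom1, start1, end1, chrom2, start2, end2,
                     name = NULL, support = NA_integer_) {
  n <- length(chrom1)
  start1 <- as.integer(start1); end1 <- as.integer(end1)
  start2 <- as.integer(start2); end2 <- as.integer(end2)
  .assert(all(end1 > start1) && all(end2 > start2) &&
            all(start1 >= 0) && all(start2 >= 0),
          "loop anchors must be valid half-open intervals")
  if (is.null(name)) name <- sprintf("loop_%d", seq_len(n))
  swap <- (chrom2 < chrom1) | (chrom2 == chrom1 & start2 < start1)
  df <- data.frame(chrom1 = ifelse(swap, chrom2, chrom1),
                   start1 = ifelse(swap, start2, start1),
                   end1 = ifelse(swap, end2, end1),
                   chrom2 = ifelse(swap, chrom1, chrom2),
                   start2 = ifelse(swap, start1, start2),
                   end2 = ifelse(swap, end1, end2),
                   name = as.character(name),
                   support = rep_len(as.integer(support), n),
                   stringsAsFactors = FALSE)
  structure(df, class = c("LoopSet", "data.frame"))
}

#' Read chromatin loops from a BEDPE file
#'
#' Expects >= 6 tab-separated columns (two anchors); column 7 is taken as
#' the loop name and column 8, when numeric, as PET support. Anchors out of
#' genome order are normalized. Malformed coordinates raise an error naming
#' the line.
#'
#' @param path path to a BEDPE file.
#' @return a \code{LoopSet}.
#' @export
read_bedpe <- function(path) {
  tab <- .read_tab_lines(path, 6L)
  n <- length(tab$fields)
  if (n == 0L) {
    return(loop_set(character(0), integer(0), integer(0),
                    character(0), integer(0), integer(0)))
  }
  chrom1 <- .tab_col(tab, 1L); chrom2 <- .tab_col(tab, 4L)
  start1 <- .tab_int(tab, 2L, path, "start1")
  end1 <- .tab_int(tab, 3L, path, "end1")
  start2 <- .tab_int(tab, 5L, path, "start2")
  end2 <- .tab_int(tab, 6L, path, "end2")
  .check_coords(start1, end1, tab, path)
  .check_coords(start2, end2, tab, path)
  name <- vapply(seq_len(n), function(i) {
    f <- tab$fields[[i]]
    if (length(f) >= 7L) f[[7L]] else sprintf("loop_%d", i)
  }, character(1L))
  support <- vapply(seq_len(n), function(i) {
    f <- tab$fields[[i]]
    if (length(f) >= 8L) suppressWarnings(as.integer(f[[8L]])) else NA_integer_
  }, integer(1L))
  loop_set(chrom1, start1, end1, chrom2, start2, end2,
           name = name, support = support)
}

#' Write loops as BEDPE
#'
#' @param loops a \code{LoopSet}.
#' @param path output path.
#' @export
write_bedpe <- function(loops, path) {
  df <- as.data.frame(loops)
  sup <- ifelse(is.na(df$support), ".", as.character(df$support))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%s",
                     df$chrom1, df$start1, df$end1,
                     df$chrom2, df$start2, df$end2, df$name, sup), path)
  invisible(path)
}

#' Stratify peaks by the number of chromatin loops they intersect
#'
#' A loop contributes one interaction to a peak's count when the peak
#' overlaps either of its anchors (>= \code{min_overlap} bp); a peak
#' touching both anchors of the same loop still counts that loop once.
#' Peaks are stratified into the three interaction groups
#' \code{">=2"}, \code{"1"} and \code{"0"}.
#'
#' @param peaks a \code{PeakSet}.
#' @param loops a \code{LoopSet}.
#' @param min_overlap minimum anchor overlap in bp (default 1).
#' @return data frame of class \code{LoopStratification} with columns
#'   \code{name}, \code{loop_count}, \code{stratum} (factor with levels
#'   \code{"0"}, \code{"1"}, \code{">=2"}).
#' @export
loop_count_stratify <- function(peaks, loops, min_overlap = 1L) {
  counts <- integer(nrow(peaks))
  if (nrow(loops) > 0L && nrow(peaks) > 0L) {
    pg <- .peaks_gr(peaks)
    a1 <- .intervals_gr(loops$chrom1, loops$start1, loops$end1)
    a2 <- .intervals_gr(loops$chrom2, loops$start2, loops$end2)
    h1 <- .fo(pg, a1, min_overlap)
    h2 <- .fo(pg, a2, min_overlap)
    pairs <- unique(rbind(
      cbind(S4Vectors::queryHits(h1), S4Vectors::subjectHits(h1)),
      cbind(S4Vectors::queryHits(h2), S4Vectors::subjectHits(h2))))
    if (nrow(pairs)) counts <- tabulate(pairs[, 1L], nbins = nrow(peaks))
  }
  stratum <- factor(ifelse(counts >= 2L, ">=2", as.character(counts)),
                    levels = .STRATA)
  structure(data.frame(name = peaks$name, loop_count = counts,
                       stratum = stratum, stringsAsFactors = FALSE),
            class = c("LoopStratification", "data.frame"))
}

#' Pairwise binding-intensity comparison across loop strata
#'
#' Two-sided Mann-Whitney tests of summit RPKM between the interaction
#' strata (>=2 vs 1, >=2 vs 0, 1 vs 0). Comparisons with an empty stratum
#' are reported as NA with a warning.
#'
#' @param rpkm data frame from \code{\link{rpkm_summit}} (columns
#'   \code{name}, \code{rpkm}).
#' @param strat a \code{LoopStratification} over the same peaks.
#' @return data frame with one row per comparison: group labels, sizes,
#'   medians, U, p and the significance ladder.
#' @export
compare_intensity_by_stratum <- function(rpkm, strat) {
  m <- merge(rpkm, as.data.frame(strat), by = "name")
  .assert(nrow(m) == nrow(rpkm), "every quantified peak needs a stratum")
  pairs <- list(c(">=2", "1"), c(">=2", "0"), c("1", "0"))
  rows <- lapply(pairs, function(pr) {
    xa <- m$rpkm[m$stratum == pr[1L]]
    xb <- m$rpkm[m$stratum == pr[2L]]
    if (!length(xa) || !length(xb)) {
      warning(sprintf("empty stratum in comparison %s vs %s", pr[1L], pr[2L]))
      return(data.frame(group_a = pr[1L], group_b = pr[2L],
                        n_a = length(xa), n_b = length(xb),
                        median_a = NA_real_, median_b = NA_real_,
                        U = NA_real_, p = NA_real_, stars = NA_character_,
                        stringsAsFactors = FALSE))
    }
    mw <- mann_whitney(xa, xb)
    data.frame(group_a = pr[1L], group_b = pr[2L],
               n_a = mw$n1, n_b = mw$n2,
               median_a = stats::median(xa), median_b = stats::median(xb),
               U = mw$statistic, p = mw$p, stars = signif_stars(mw$p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Construct a super-enhancer region set
#'
#' Mother (pre-established) and daughter (induced) constituent regions of
#' super-enhancers, each linked to a super-enhancer id.
#'
#' @param chrom,start,end region intervals (0-based half-open).
#' @param se_id super-enhancer identifiers.
#' @param role \code{"mother"} or \code{"daughter"} per region.
#' @return data frame of class \code{SERegionSet}.
#' @export
se_region_set <- function(chrom, start, end, se_id, role) {
  start <- as.integer(start); end <- as.integer(end)
  .assert(all(end > start) && all(start >= 0), "invalid SE region interval")
  .assert(all(role %in% c("mother", "daughter")),
          "role must be 'mother' or 'daughter'")
  structure(data.frame(chrom = as.character(chrom), start = start, end = end,
                       se_id = as.character(se_id), role = as.character(role),
                       stringsAsFactors = FALSE),
            class = c("SERegionSet", "data.frame"))
}

#' Read super-enhancer regions from BED6
#'
#' The name field encodes the super-enhancer id and the role as
#' \code{"SEid:mother"} or \code{"SEid:daughter"}.
#'
#' @param path path to the BED file.
#' @return an \code{SERegionSet}.
#' @export
read_se_regions <- function(path) {
  tab <- .read_tab_lines(path, 4L)
  chrom <- .tab_col(tab, 1L)
  start <- .tab_int(tab, 2L, path, "start")
  end <- .tab_int(tab, 3L, path, "end")
  .check_coords(start, end, tab, path)
  name <- .tab_col(tab, 4L)
  parts <- strsplit(name, ":", fixed = TRUE)
  ok <- lengths(parts) == 2L
  if (!all(ok)) {
    stop(sprintf("%s: line %d: name '%s' is not of the form SEid:role",
                 path, tab$lineno[which(!ok)[1L]], name[which(!ok)[1L]]),
         call. = FALSE)
  }
  se_region_set(chrom, start, end,
                se_id = vapply(parts, `[[`, character(1L), 1L),
                role = vapply(parts, `[[`, character(1L), 2L))
}

#' Write super-enhancer regions as BED6
#'
#' @param se an \code{SERegionSet}.
#' @param path output path.
#' @export
write_se_regions <- function(se, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s:%s\t0\t.", se$chrom, se$start, se$end,
                     se$se_id, se$role), path)
  invisible(path)
}

#' Fraction of SE regions occupied by loop-associated peaks
#'
#' A region counts as positive when it overlaps at least one peak whose
#' chromatin-interaction count is at least \code{min_loops} (default 1,
#' i.e. peaks correlated with any ERa-mediated interaction). Percentages
#' are reported per role at two-decimal precision.
#'
#' @param se an \code{SERegionSet} with both roles present.
#' @param peaks the \code{PeakSet} the stratification was computed on.
#' @param strat a \code{LoopStratification} over \code{peaks}.
#' @param min_loops minimum loop count for a peak to qualify (default 1).
#' @return data frame with columns \code{role}, \code{n}, \code{positive},
#'   \code{percent}.
#' @export
se_overlap_fraction <- function(se, peaks, strat, min_loops = 1L) {
  .assert(identical(sort(strat$name), sort(peaks$name)),
          "stratification must be computed on the same PeakSet")
  for (r in c("mother", "daughter")) {
    if (!any(se$role == r)) stop(sprintf("no regions with role '%s'", r),
                                 call. = FALSE)
  }
  counts <- strat$loop_count[match(peaks$name, strat$name)]
  qual <- which(counts >= min_loops)
  pos <- logical(nrow(se))
  if (length(qual)) {
    rg <- .intervals_gr(se$chrom, se$start, se$end)
    pg <- .peaks_gr(.subset_peaks(peaks, qual))
    hits <- .fo(rg, pg)
    pos[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  out <- do.call(rbind, lapply(c("mother", "daughter"), function(r) {
    idx <- se$role == r
    data.frame(role = r, n = sum(idx), positive = sum(pos & idx),
               percent = round(100 * sum(pos & idx) / sum(idx), 2L),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
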