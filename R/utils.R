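`%||%` <- function(x, y) if (is.null(x)) y else x

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  .assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
          "seed must be a single finite number")
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Read a tab-separated text file, skipping comment/track lines, keeping
# original line numbers so parse errors can cite them.
.read_tab_lines <- function(path, min_cols) {
  .assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !grepl("^(#|track\\b|browser\\b)", lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  nf <- lengths(fields)
  if (any(nf < min_cols)) {
    bad <- lineno[which(nf < min_cols)[1L]]
    stop(sprintf("%s: line %d has fewer than %d tab-separated columns",
                 path, bad, min_cols), call. = FALSE)
  }
  list(fields = fields, lineno = lineno)
}

# Extract column j from a strsplit() result as character.
.tab_col <- function(tab, j) {
  vapply(tab$fields, `[[`, character(1L), j)
}

.tab_int <- function(tab, j, path, what) {
  raw <- .tab_col(tab, j)
  val <- suppressWarnings(as.numeric(raw))
  bad <- is.na(val) | val != floor(val)
  if (any(bad)) {
    stop(sprintf("%s: line %d: %s '%s' is not an integer",
                 path, tab$lineno[which(bad)[1L]], what, raw[which(bad)[1L]]),
         call. = FALSE)
  }
  as.integer(val)
}

.check_coords <- function(start, end, tab, path) {
  bad <- end <= start | start < 0L
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("%s: line %d: invalid interval [%d, %d) (need 0 <= start < end)",
                 path, tab$lineno[i], start[i], end[i]), call. = FALSE)
  }
  invisible(NULL)
}

#' Significance ladder used throughout reports
#'
#' Renders p-values with the conventional asterisk ladder
#' (\code{*} p < 0.05, \code{**} p < 0.01, \code{***} p < 0.001,
#' \code{****} p < 0.0001, \code{ns} otherwise).
#'
#' @param p numeric vector of p-values.
#' @return character vector of the same length.
#' @export
signif_stars <- function(p) {
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[p < 0.0001] <- "****"
  out[is.na(p)] <- NA_character_
  out
}

# findOverlaps over GRanges built from plain coordinate sets; suppresses the
# benign seqlevels-merge warning raised when the two sets live on disjoint
# chromosome name universes.
.fo <- function(gr1, gr2, minoverlap = 1L) {
  suppressWarnings(GenomicRanges::findOverlaps(
    gr1, gr2, minoverlap = as.integer(minoverlap)))
}
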