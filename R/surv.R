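# Median-split group assignment, Kaplan-Meier estimation and the logrank
# (Mantel-Cox) test for expression-stratified cohorts.

#' Median split into high/low expression groups
#'
#' Labels records \code{"high"} when their value exceeds the sample median
#' and \code{"low"} otherwise: ties at the median go to the low group (so
#' an odd-sized sample puts its middle value in the low group). The split
#' quantile is configurable.
#'
#' @param values numeric vector (>= 2 records, not all identical).
#' @param quantile split quantile (default 0.5, the median).
#' @return factor with levels \code{low}, \code{high}.
#' @export
median_split <- function(values, quantile = 0.5) {
  .assert(length(values) >= 2L, "need at least 2 records")
  cut <- stats::quantile(values, quantile, names = FALSE, type = 7)
  if (all(values == values[1L])) {
    stop("degenerate split: all values identical", call. = FALSE)
  }
  factor(ifelse(values > cut, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function; censored-only times do
#' not drop the curve. Computation is delegated to
#' \code{survival::survfit}.
#'
#' @param time follow-up times (> 0).
#' @param event event indicators (1 = event, 0 = censored).
#' @return data frame of class \code{KMCurve} with columns \code{time},
#'   \code{n_risk}, \code{n_event}, \code{surv}.
#' @export
km_curve <- function(time, event) {
  .assert(length(time) >= 1L, "need at least one record")
  .assert(all(time > 0), "times must be > 0")
  .assert(all(event %in% c(0, 1)), "event must be 0 or 1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, surv = fit$surv),
            class = c("KMCurve", "data.frame"))
}

#' Logrank (Mantel-Cox) test
#'
#' Observed-minus-expected statistic summed over distinct event times,
#' referred to the chi-square distribution with one degree of freedom.
#' Computation is delegated to \code{survival::survdiff}.
#'
#' @param time follow-up times (> 0).
#' @param event event indicators (1 = event, 0 = censored).
#' @param group two-level factor or character vector of group labels.
#' @return list with \code{chi2}, \code{p}, \code{df} (= 1) and per-group
#'   observed/expected event counts.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  .assert(nlevels(group) == 2L, "exactly two groups are required")
  .assert(all(table(group) >= 1L), "both groups must be non-empty")
  .assert(sum(event) >= 1, "at least one event is required")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       df = 1L, observed = unname(sd$obs), expected = unname(sd$exp))
}

#' Read a cohort table from TSV
#'
#' Expects columns \code{patient}, \code{time}, \code{event},
#' \code{expression_z}, plus optional subgroup columns.
#'
#' @param path path to the cohort TSV.
#' @return data frame.
#' @export
read_cohort_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient", "time", "event", "expression_z")
  miss <- setdiff(need, names(df))
  .assert(length(miss) == 0, "cohort table lacks column(s): %s",
          paste(miss, collapse = ", "))
  .assert(all(df$time > 0), "times must be > 0")
  .assert(all(df$event %in% c(0, 1)), "event must be 0 or 1")
  df
}
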