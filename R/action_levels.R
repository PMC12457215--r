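#' Linear-interpolation percentile
#'
#' The package-wide percentile convention: linear interpolation between order
#' statistics with inclusive endpoints (R's `quantile` type 7). Under it the
#' median of 1..5 is 3 and the 25th percentile of \{10, 20, 30, 40\} is 17.5.
#'
#' @param values non-empty numeric vector.
#' @param p proportion in \[0, 1\].
#' @return The p-quantile.
#' @export
qa_percentile <- function(values, p) {
  if (length(values) == 0)
    stop("qa_percentile: empty-statistics error", call. = FALSE)
  if (any(p < 0 | p > 1))
    stop("qa_percentile: `p` must be in [0, 1]", call. = FALSE)
  unname(quantile(values, p, type = 7, names = FALSE))
}

# round `x` to a multiple of `granularity`.
# convention "nearest": nearest multiple, ties toward the lenient side
# (`lenient_up = FALSE` rounds half-down, TRUE rounds half-up);
# convention "outward": always round to the lenient side.
round_to_multiple <- function(x, granularity, convention, lenient_up) {
  k <- x / granularity
  switch(convention,
    nearest = granularity * (if (lenient_up) floor(k + 0.5) else ceiling(k - 0.5)),
    outward = granularity * (if (lenient_up) ceiling(k - 1e-9) else floor(k + 1e-9)),
    stop("unknown rounding convention ", convention, call. = FALSE))
}

new_action_level <- function(metric, criterion, threshold, q, sidedness,
                             quantile_raw) {
  structure(list(metric = metric, criterion = criterion, threshold = threshold,
                 q = q, sidedness = sidedness, quantile_raw = quantile_raw),
            class = "action_level")
}

#' @export
print.action_level <- function(x, ...) {
  if (x$metric == "gpr")
    cat(sprintf("<action_level> %s >= %g%% (q = %g, unrounded %.3f)\n",
                x$criterion, x$threshold, x$q, x$quantile_raw))
  else
    cat(sprintf("<action_level> |dD| <= %g%% (q = %g, unrounded %.3f)\n",
                x$threshold, x$q, x$quantile_raw))
  invisible(x)
}

#' Percentile action level for a gamma pass rate
#'
#' The GPR threshold at which approximately a fraction `q` of the cohort
#' fails: the q-quantile of the cohort's GPR values, rounded to a multiple of
#' `granularity` (default 5 GPR points). A plan *fails* when its GPR is
#' strictly below the threshold. Rounding is "nearest multiple, ties toward
#' the lenient (lower) side" by default; `convention = "outward"` always
#' rounds down.
#'
#' @param gprs cohort GPR values in \[0, 100\].
#' @param q target failure rate in (0, 1).
#' @param granularity rounding step, default 5.
#' @param convention `"nearest"` or `"outward"`.
#' @param criterion label of the gamma criterion the values belong to.
#' @return An `action_level` (metric `"gpr"`, one-sided lower).
#' @export
gpr_action_level <- function(gprs, q, granularity = 5,
                             convention = c("nearest", "outward"),
                             criterion = "gpr") {
  convention <- match.arg(convention)
  if (q <= 0 || q >= 1)
    stop("gpr_action_level: parameter error, q must be in (0, 1)", call. = FALSE)
  raw <- qa_percentile(gprs, q)
  thr <- round_to_multiple(raw, granularity, convention, lenient_up = FALSE)
  thr <- min(thr, 100)
  new_action_level("gpr", criterion, thr, q, "one_sided_lower", raw)
}

#' Percentile action level for the absolute mean target dose difference
#'
#' Threshold on \eqn{|\Delta D|} at which approximately a fraction `q` of
#' the cohort fails: the (1-q)-quantile of \eqn{|\Delta D|}, rounded to a
#' multiple of `granularity` (default 0.5 percentage points). A plan *fails*
#' when \eqn{|\Delta D|} is strictly above the threshold. Default rounding is
#' nearest-multiple with ties toward the lenient (higher) side;
#' `convention = "outward"` always rounds up.
#'
#' @param dds cohort of signed \eqn{\Delta D} values (%).
#' @param q target failure rate in (0, 1).
#' @param granularity rounding step, default 0.5.
#' @param convention `"nearest"` or `"outward"`.
#' @return An `action_level` (metric `"dd"`, two-sided on the absolute value).
#' @export
dd_action_level <- function(dds, q, granularity = 0.5,
                            convention = c("nearest", "outward")) {
  convention <- match.arg(convention)
  if (q <= 0 || q >= 1)
    stop("dd_action_level: parameter error, q must be in (0, 1)", call. = FALSE)
  raw <- qa_percentile(abs(dds), 1 - q)
  thr <- round_to_multiple(raw, granularity, convention, lenient_up = TRUE)
  thr <- max(thr, granularity)   # degenerate cohorts floor at one step
  new_action_level("dd", "abs_delta_d", thr, q, "two_sided_abs", raw)
}

#' Construct a fixed (user-chosen) action level
#'
#' @param metric `"gpr"` or `"dd"`.
#' @param threshold the threshold (GPR % or |dD| %).
#' @param criterion for GPR levels, the criterion column label
#'   (e.g. `"gpr_3_3"`).
#' @param q nominal failure rate to record, if any.
#' @return An `action_level`.
#' @export
fixed_action_level <- function(metric = c("gpr", "dd"), threshold,
                               criterion = "gpr", q = NA_real_) {
  metric <- match.arg(metric)
  new_action_level(metric, if (metric == "dd") "abs_delta_d" else criterion,
                   threshold, q,
                   if (metric == "gpr") "one_sided_lower" else "two_sided_abs",
                   threshold)
}

# fail flags for an action level on a cohort data frame
al_fails <- function(cohort, al, use_raw = FALSE) {
  thr <- if (use_raw) al$quantile_raw else al$threshold
  if (al$metric == "gpr") {
    col <- al$criterion
    if (!col %in% names(cohort))
      stop("observed_failure_rate: data error, missing column ", col, call. = FALSE)
    v <- cohort[[col]]
    if (any(!is.finite(v)))
      stop("observed_failure_rate: data error, non-finite GPR", call. = FALSE)
    v < thr
  } else {
    if (!"delta_d" %in% names(cohort))
      stop("observed_failure_rate: data error, missing delta_d", call. = FALSE)
    abs(cohort$delta_d) > thr
  }
}

#' Observed failure rate of a cohort at an action level
#'
#' @param cohort plan-results data frame (see [write_plan_results()]).
#' @param al an `action_level`.
#' @param use_raw apply the unrounded percentile threshold instead of the
#'   rounded one.
#' @return Percentage of plans failing the criterion.
#' @export
observed_failure_rate <- function(cohort, al, use_raw = FALSE) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0)
    stop("observed_failure_rate: empty-statistics error", call. = FALSE)
  100 * mean(al_fails(cohort, al, use_raw))
}

#' Combined-criteria 2x2 tabulation
#'
#' A plan fails the *combined* criterion only when it fails both the gamma
#' action level and the \eqn{|\Delta D|} action level. Marginal percentages
#' include the joint cell, so the identity
#' `passed_both = 100 - failed_gamma - failed_dd + failed_both` holds exactly.
#'
#' @param cohort plan-results data frame.
#' @param al_gamma a GPR `action_level`.
#' @param al_dd a \eqn{|\Delta D|} `action_level`.
#' @return Object of class `combined_table` with fields `passed_both`,
#'   `failed_both`, `failed_gamma`, `failed_dd` (percent) and `n`.
#' @export
combined_table <- function(cohort, al_gamma, al_dd) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0)
    stop("combined_table: empty-statistics error", call. = FALSE)
  fg <- al_fails(cohort, al_gamma)
  fd <- al_fails(cohort, al_dd)
  n <- nrow(cohort)
  structure(list(passed_both = 100 * sum(!fg & !fd) / n,
                 failed_both = 100 * sum(fg & fd) / n,
                 failed_gamma = 100 * sum(fg) / n,
                 failed_dd = 100 * sum(fd) / n,
                 n = n),
            class = "combined_table")
}

#' @export
print.combined_table <- function(x, ...) {
  cat(sprintf(paste0("<combined_table> n = %d\n  passed both  %5.1f%%\n",
                     "  failed both  %5.1f%%\n  failed gamma %5.1f%%\n",
                     "  failed |dD|  %5.1f%%\n"),
              x$n, x$passed_both, x$failed_both, x$failed_gamma, x$failed_dd))
  invisible(x)
}

#' Action-level table for a cohort
#'
#' Derives percentile action levels for every GPR column and for
#' \eqn{|\Delta D|} at each failure rate in `q`, mirroring the study's
#' action-level report.
#'
#' @param cohort plan-results data frame.
#' @param q failure rates, default `c(0.02, 0.05, 0.1, 0.2)`.
#' @param convention rounding convention, see [gpr_action_level()].
#' @return `data.frame` with columns `metric, criterion, q, threshold,
#'   quantile_raw, observed_fail_pct`.
#' @export
action_level_table <- function(cohort, q = c(0.02, 0.05, 0.1, 0.2),
                               convention = "nearest") {
  check_cohort(cohort)
  rows <- list()
  for (qi in q) {
    for (col in gpr_columns(cohort)) {
      al <- gpr_action_level(cohort[[col]], qi, convention = convention,
                             criterion = col)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = "gpr", criterion = col, q = qi, threshold = al$threshold,
        quantile_raw = al$quantile_raw,
        observed_fail_pct = observed_failure_rate(cohort, al))
    }
    al <- dd_action_level(cohort$delta_d, qi, convention = convention)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "dd", criterion = "abs_delta_d", q = qi, threshold = al$threshold,
      quantile_raw = al$quantile_raw,
      observed_fail_pct = observed_failure_rate(cohort, al))
  }
  do.call(rbind, rows)
}
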