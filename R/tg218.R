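#' TG-218 action-interval parameters
#'
#' Houses the symbols of the TG-218 tolerance/action-limit formalism:
#' the QA target value `T` (100 for a gamma pass rate, 0 for a dose
#' difference), the observed cohort mean `xbar` and standard deviation
#' `sigma`, and the dimensionless multiplier `beta`.
#'
#' @param target QA target value `T`.
#' @param xbar observed mean of the QA results.
#' @param sigma observed standard deviation (>= 0).
#' @param beta multiplier (> 0); the tentative TG-218 recommendation is 6,
#'   i.e. a failure is a 3-sigma event when systematic error vanishes.
#' @return Object of class `tg218_params`.
#' @export
tg218_params <- function(target, xbar, sigma, beta = 6) {
  if (!is.finite(sigma) || sigma < 0)
    stop("tg218_params: sigma must be >= 0", call. = FALSE)
  if (!is.finite(beta) || beta <= 0)
    stop("tg218_params: parameter error, beta must be > 0", call. = FALSE)
  structure(list(target = target, xbar = xbar, sigma = sigma, beta = beta),
            class = "tg218_params")
}

#' TG-218 action interval
#'
#' The interval half-width is
#' \deqn{A = (\beta/2)\sqrt{\sigma^2 + (\bar{x} - T)^2},}
#' combining the random (\eqn{\sigma}) and systematic (\eqn{\bar{x}-T})
#' components of the QA process. The action levels are `T - A` and `T + A`
#' for a two-sided metric; one-sided metrics such as a gamma pass rate use
#' only `T - A`.
#'
#' @param p a [tg218_params()].
#' @return Named numeric `c(lower, upper)`.
#' @examples
#' action_interval(tg218_params(100, 100, 2, beta = 6))  # lower level 94
#' @export
action_interval <- function(p) {
  stopifnot(inherits(p, "tg218_params"))
  A <- (p$beta / 2) * sqrt(p$sigma^2 + (p$xbar - p$target)^2)
  c(lower = p$target - A, upper = p$target + A)
}

#' Convert a QA failure rate to the TG-218 factor beta/2
#'
#' Assuming normally distributed QA results, the factor is the standard
#' normal quantile with upper-tail probability `q` (one-sided metrics such
#' as GPR) or `q/2` (two-sided metrics such as \eqn{\Delta D}).
#'
#' @param q failure rate in (0, 1).
#' @param sidedness `"one_sided"` or `"two_sided"`.
#' @return The factor \eqn{\beta/2}.
#' @export
beta_half_from_q <- function(q, sidedness = c("one_sided", "two_sided")) {
  sidedness <- match.arg(sidedness)
  if (any(q <= 0 | q >= 1))
    stop("beta_half_from_q: parameter error, q must be in (0, 1)", call. = FALSE)
  if (sidedness == "one_sided") qnorm(1 - q) else qnorm(1 - q / 2)
}

#' Inverse of [beta_half_from_q()]
#'
#' @param b factor \eqn{\beta/2 \ge 0}.
#' @param sidedness `"one_sided"` or `"two_sided"`.
#' @return The failure rate `q`.
#' @export
q_from_beta_half <- function(b, sidedness = c("one_sided", "two_sided")) {
  sidedness <- match.arg(sidedness)
  if (any(b < 0))
    stop("q_from_beta_half: parameter error, beta/2 must be >= 0", call. = FALSE)
  if (sidedness == "one_sided") 1 - pnorm(b) else 2 * (1 - pnorm(b))
}

#' Expected failure rate at an action level under a Gaussian model
#'
#' For a one-sided lower level (GPR) the expected fraction failing is
#' \eqn{\Phi((t - \bar{x})/\sigma)}; for a two-sided level on
#' \eqn{|\Delta D|} it is \eqn{1 - \Phi((t-\bar{x})/\sigma) +
#' \Phi((-t-\bar{x})/\sigma)}.
#'
#' @param mean,sd cohort mean and standard deviation of the metric.
#' @param threshold the action level (GPR % or |dD| % depending on
#'   `sidedness`).
#' @param sidedness `"one_sided"` (fail below threshold) or `"two_sided"`
#'   (fail when the absolute value exceeds threshold).
#' @return Expected failure rate in percent.
#' @examples
#' expected_fail_rate(1.75, 2.41, 4.5, "two_sided")  # ~13.2
#' @export
expected_fail_rate <- function(mean, sd, threshold,
                               sidedness = c("one_sided", "two_sided")) {
  sidedness <- match.arg(sidedness)
  if (sd < 0) stop("expected_fail_rate: sd must be >= 0", call. = FALSE)
  if (sd == 0) {
    fail <- if (sidedness == "one_sided") mean < threshold
            else abs(mean) > threshold
    return(100 * as.numeric(fail))
  }
  if (sidedness == "one_sided")
    100 * pnorm((threshold - mean) / sd)
  else
    100 * (1 - pnorm((threshold - mean) / sd) + pnorm((-threshold - mean) / sd))
}

#' Binomial standard error of an observed proportion
#'
#' @param p proportion in \[0, 1\].
#' @param n cohort size (>= 1).
#' @return Standard error in percentage points, `100 * sqrt(p (1-p) / n)`.
#' @export
binomial_se <- function(p, n) {
  stopifnot(all(p >= 0 & p <= 1), all(n >= 1))
  100 * sqrt(p * (1 - p) / n)
}

# closed-form mean and variance of min(X, bound) for X ~ N(mu, sigma)
clipped_normal_moments <- function(mu, sigma, bound = 100) {
  a <- (bound - mu) / sigma
  P <- pnorm(a); phi <- dnorm(a)
  m1 <- mu * P - sigma * phi + bound * (1 - P)
  m2 <- (mu^2 + sigma^2) * P - sigma * (mu + bound) * phi + bound^2 * (1 - P)
  c(mean = m1, var = m2 - m1^2)
}

# latent N(mu, sigma) such that min(X, bound) has the target mean and sd
match_clipped_normal <- function(target_mean, target_sd, bound = 100) {
  if (target_mean >= bound)
    stop("parameter error: target mean must lie below the truncation bound",
         call. = FALSE)
  if (target_sd <= 0)
    stop("parameter error: target sd must be positive", call. = FALSE)
  obj <- function(par) {
    mo <- clipped_normal_moments(par[1], exp(par[2]), bound)
    (mo["mean"] - target_mean)^2 + (sqrt(max(mo["var"], 0)) - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               control = list(reltol = 1e-14, maxit = 5000))
  mo <- clipped_normal_moments(fit$par[1], exp(fit$par[2]), bound)
  err <- max(abs(mo["mean"] - target_mean), abs(sqrt(mo["var"]) - target_sd))
  if (!is.finite(err) || err > 1e-3 * max(target_sd, 1))
    stop("parameter error: infeasible moment match for clipped Gaussian",
         call. = FALSE)
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Sample a right-truncated (clipped) GPR distribution
#'
#' Latent Gaussian clipped at the bound (default 100), with the latent
#' parameters moment-matched so the *clipped* variable has the requested
#' mean and standard deviation.
#'
#' @param n number of samples.
#' @param mean,sd target mean and standard deviation of the clipped variable.
#' @param bound truncation bound, default 100.
#' @return Numeric vector of samples `<= bound`.
#' @export
sample_clipped_gpr <- function(n, mean, sd, bound = 100) {
  fit <- match_clipped_normal(mean, sd, bound)
  pmin(rnorm(n, fit$mu, fit$sigma), bound)
}

#' Truncation correction factor for the one-sided beta/2
#'
#' Gamma pass rates cannot exceed 100, so their distribution near the bound
#' is asymmetric with a heavy left tail and the Gaussian q-to-beta/2
#' conversion underestimates the quantile distance. This operation simulates
#' a clipped-Gaussian GPR cohort moment-matched to (`gpr_mean`, `gpr_sd`),
#' measures the empirical standardized quantile distance
#' \eqn{(\bar{x} - Q_q)/s}, and returns its ratio to the untruncated Gaussian
#' \eqn{\beta/2} for the same `q`. Factors > 1 mean the Gaussian conversion
#' is too lenient; far from the bound the factor tends to 1.
#'
#' @param gpr_mean,gpr_sd target cohort mean (must be < 100) and SD.
#' @param q failure rate in (0, 1).
#' @param reps number of simulated plans, at least 1e4.
#' @param seed RNG seed for reproducibility.
#' @return The correction factor (dimensionless).
#' @export
truncation_beta_correction <- function(gpr_mean, gpr_sd, q, reps = 1e5,
                                       seed = 1) {
  if (gpr_mean > 100)
    stop("truncation_beta_correction: parameter error, mean must be <= 100",
         call. = FALSE)
  if (reps < 1e4)
    stop("truncation_beta_correction: reps must be >= 1e4", call. = FALSE)
  if (q <= 0 || q >= 1)
    stop("truncation_beta_correction: parameter error, q must be in (0, 1)",
         call. = FALSE)
  set.seed(seed)
  x <- sample_clipped_gpr(reps, gpr_mean, gpr_sd)
  b_emp <- (mean(x) - qa_percentile(x, q)) / sd(x)
  b_emp / beta_half_from_q(q, "one_sided")
}

#' TG-218 report table for a cohort
#'
#' For each GPR column and for \eqn{\Delta D}, and each failure rate in `q`:
#' the Gaussian factor \eqn{\beta/2}, the TG-218 action level from the
#' cohort mean/SD via [action_interval()], the expected failure rate at the
#' *percentile* action level derived from the same cohort, and its binomial
#' standard error.
#'
#' @param cohort plan-results data frame.
#' @param q failure rates.
#' @param convention rounding convention for the percentile levels.
#' @return `data.frame` with one row per metric and q.
#' @export
tg218_table <- function(cohort, q = c(0.02, 0.05, 0.1, 0.2),
                        convention = "nearest") {
  check_cohort(cohort)
  n <- nrow(cohort)
  rows <- list()
  for (qi in q) {
    for (col in gpr_columns(cohort)) {
      m <- mean(cohort[[col]]); s <- sd(cohort[[col]])
      bh <- beta_half_from_q(qi, "one_sided")
      ai <- action_interval(tg218_params(100, m, s, beta = 2 * bh))
      al <- gpr_action_level(cohort[[col]], qi, convention = convention,
                             criterion = col)
      ef <- expected_fail_rate(m, s, al$threshold, "one_sided")
      rows[[length(rows) + 1L]] <- data.frame(
        metric = "gpr", criterion = col, q = qi, beta_half = bh,
        tg218_level = ai[["lower"]], percentile_level = al$threshold,
        expected_fail_pct = ef, binomial_se_pct = binomial_se(ef / 100, n),
        observed_fail_pct = observed_failure_rate(cohort, al))
    }
    m <- mean(cohort$delta_d); s <- sd(cohort$delta_d)
    bh <- beta_half_from_q(qi, "two_sided")
    ai <- action_interval(tg218_params(0, m, s, beta = 2 * bh))
    al <- dd_action_level(cohort$delta_d, qi, convention = convention)
    ef <- expected_fail_rate(m, s, al$threshold, "two_sided")
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "dd", criterion = "abs_delta_d", q = qi, beta_half = bh,
      tg218_level = ai[["upper"]], percentile_level = al$threshold,
      expected_fail_pct = ef, binomial_se_pct = binomial_se(ef / 100, n),
      observed_fail_pct = observed_failure_rate(cohort, al))
  }
  do.call(rbind, rows)
}
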