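#' Fit the random-slope trend model for MOS over time
#'
#' Linear mixed-effects model `mos = b0 + b1 * time + b0_i + b1_i * time + e`
#' with correlated patient-level random intercepts and slopes, fitted by
#' REML via [lme4::lmer()]. Time is the 6-month interval index, so the
#' fixed slope is the average MOS change in percentage points per interval.
#' If the random-effects covariance is singular, the model is refitted with
#' the intercept-slope correlation fixed at zero and the result is flagged.
#'
#' @param data Long tibble with columns `id`, `time`, `mos`.
#' @param conf_level Confidence level for the fixed effects (Wald).
#' @param random_slope If `FALSE`, fit the random-intercept-only reduced
#'   model (the comparator of [lrt_random_slope()]).
#' @return Object of class `hfmos_lmm`: list with the `lmerMod` fit and
#'   fields `fixed` (tibble: term, estimate, se, conf_low, conf_high),
#'   `sd_intercept`, `sd_slope`, `cor_intercept_slope`, `sd_resid`,
#'   `loglik` (REML criterion), `n_patients`, `n_obs`,
#'   `uncorrelated_refit` flag.
#' @export
fit_lmm <- function(data, conf_level = 0.95, random_slope = TRUE) {
  data <- as_tibble(data)
  per_pat <- data |> count(.data$id)
  if (max(per_pat$n) < 2) {
    abort("Slope is inestimable: no patient has more than one observation.")
  }
  form <- if (random_slope) mos ~ time + (time | id) else mos ~ time + (1 | id)
  fit <- suppressMessages(
    suppressWarnings(lme4::lmer(form, data = data, REML = TRUE)))
  refit_flag <- FALSE
  if (random_slope && lme4::isSingular(fit, tol = 1e-4)) {
    fit <- suppressMessages(
      suppressWarnings(lme4::lmer(mos ~ time + (time || id), data = data, REML = TRUE)))
    refit_flag <- TRUE
  }
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- qnorm(1 - (1 - conf_level) / 2)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_int <- vc$sdcor[vc$grp %in% c("id", "id.1") & vc$var1 == "(Intercept)" & is.na(vc$var2)][1]
  sd_slp <- vc$sdcor[vc$grp %in% c("id", "id.1") & vc$var1 == "time" & is.na(vc$var2)][1]
  cor_is <- if (refit_flag) 0 else {
    i <- which(vc$grp == "id" & !is.na(vc$var2) & vc$var1 == "(Intercept)" &
                 vc$var2 == "time")
    if (length(i)) vc$sdcor[i[1]] else 0
  }
  structure(
    list(
      fit = fit,
      fixed = tibble(term = names(fe), estimate = unname(fe), se = se,
                     conf_low = unname(fe) - z * se,
                     conf_high = unname(fe) + z * se),
      sd_intercept = sd_int, sd_slope = sd_slp,
      cor_intercept_slope = cor_is,
      sd_resid = vc$sdcor[vc$grp == "Residual"][1],
      loglik = as.numeric(logLik(fit)),
      n_patients = n_distinct(data$id), n_obs = nrow(data),
      uncorrelated_refit = refit_flag
    ),
    class = "hfmos_lmm"
  )
}

#' @export
print.hfmos_lmm <- function(x, ...) {
  cat(sprintf("Random-slope trend model: %d patients, %d observations\n",
              x$n_patients, x$n_obs))
  print(x$fixed)
  cat(sprintf("Random effects SD: intercept %.2f, slope %.2f (cor %.2f); residual %.2f\n",
              x$sd_intercept, x$sd_slope, x$cor_intercept_slope, x$sd_resid))
  invisible(x)
}

#' Likelihood-ratio test for random slopes
#'
#' Compares the random-intercept-only model against the random-slope model
#' fitted to the same data with the same fixed effects, refitting both by
#' maximum likelihood. Because the null (slope variance = 0) lies on the
#' boundary of the parameter space, the p-value uses the 50:50 mixture of
#' chi-square distributions with 1 and 2 degrees of freedom. Passing the
#' same model twice gives statistic 0 and p = 1.
#'
#' @param fit_intercept_only,fit_full `hfmos_lmm` (or `lmerMod`) fits of the
#'   reduced and full model. The fixed-effect formulas must agree and the
#'   random structures must be nested.
#' @return Tibble with `statistic` (2 * delta log-likelihood, floored at 0),
#'   `p_value`, `loglik_intercept`, `loglik_slope` (ML log-likelihoods).
#' @export
lrt_random_slope <- function(fit_intercept_only, fit_full) {
  get_fit <- function(x) if (inherits(x, "hfmos_lmm")) x$fit else x
  m0 <- get_fit(fit_intercept_only); m1 <- get_fit(fit_full)
  stopifnot(inherits(m0, "merMod"), inherits(m1, "merMod"))
  fixed0 <- deparse(lme4::nobars(stats::formula(m0)))
  fixed1 <- deparse(lme4::nobars(stats::formula(m1)))
  if (!identical(fixed0, fixed1)) {
    abort("Non-nested fits: fixed-effect formulas differ.")
  }
  n_re <- function(m) sum(vapply(lme4::VarCorr(m), function(v) nrow(v), 1L))
  if (n_re(m0) > n_re(m1)) {
    abort("Non-nested fits: the reduced model has more random effects than the full model.")
  }
  m0 <- if (lme4::isREML(m0)) lme4::refitML(m0) else m0
  m1 <- if (lme4::isREML(m1)) lme4::refitML(m1) else m1
  ll0 <- as.numeric(logLik(m0)); ll1 <- as.numeric(logLik(m1))
  stat <- max(0, 2 * (ll1 - ll0))
  p <- if (stat == 0) 1 else {
    0.5 * pchisq(stat, df = 1, lower.tail = FALSE) +
      0.5 * pchisq(stat, df = 2, lower.tail = FALSE)
  }
  tibble(statistic = stat, p_value = p, loglik_intercept = ll0, loglik_slope = ll1)
}

#' Fit both trend models and run the random-slope test
#'
#' @param data Long tibble with columns `id`, `time`, `mos`.
#' @return As [lrt_random_slope()].
#' @export
trend_lrt <- function(data) {
  f0 <- fit_lmm(data, random_slope = FALSE)
  f1 <- fit_lmm(data, random_slope = TRUE)
  lrt_random_slope(f0, f1)
}

#' Per-interval MOS distribution summary
#'
#' Mean, SD, normal-approximation CI of the mean, median and IQR of the
#' patient-level interval means - the data behind the longitudinal trend
#' figure.
#'
#' @param data Long tibble with columns `id`, `time`, `mos`.
#' @return Tibble with one row per `time`.
#' @export
summarise_mos_by_interval <- function(data) {
  as_tibble(data) |>
    group_by(.data$time) |>
    summarise(
      n = dplyr::n(), mean = mean(.data$mos), sd = sd(.data$mos),
      ci_low = mean(.data$mos) - 1.96 * sd(.data$mos) / sqrt(dplyr::n()),
      ci_high = mean(.data$mos) + 1.96 * sd(.data$mos) / sqrt(dplyr::n()),
      median = median(.data$mos),
      q25 = quantile(.data$mos, 0.25, names = FALSE),
      q75 = quantile(.data$mos, 0.75, names = FALSE),
      .groups = "drop"
    )
}
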