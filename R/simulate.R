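#' Ground-truth parameters for the synthetic cohort generator
#'
#' Bundles every coefficient of the synthetic data-generating process so that
#' downstream recovery tests can compare estimates against known truth.
#' Defaults encode the cohort conditions the package's analyses assume: a
#' baseline MOS around 56 +/- 21, an upward titration trend of 3.3
#' percentage points per 6-month interval with patient-level slope
#' heterogeneity, ordinal HF severity (HFPSI 1-4) that both influences and
#' responds to medication optimization (treatment-confounder feedback), a
#' protective exposure effect of log(0.88) per 10 MOS units on the
#' per-interval log-hazard, and loss to follow-up that increases with
#' distance from the treating center.
#'
#' @param n_patients Number of patients.
#' @param n_intervals Number of 6-month intervals (indices 0..n_intervals-1).
#' @param beta_mos_per10 True exposure effect: log-hazard per 10 MOS units.
#' @param beta_hfpsi Length-3 log-hazard vector for HFPSI levels 2-4 vs 1.
#' @param beta_cci Length-2 log-hazard vector for moderate/severe vs mild CCI.
#' @param beta_age_per10 Log-hazard per 10 years of age.
#' @param baseline_hazard Per-interval baseline hazard (> 0) at reference
#'   covariates.
#' @param titration_mean_pp Mean MOS gain per interval, percentage points.
#' @param titration_sd_pp SD of the patient-level random titration slope.
#' @param noise_sd_pp SD of the within-patient interval-to-interval MOS noise.
#' @param feedback_hfpsi_on_mos Effect of lagged severity (per level above 1)
#'   on the titration increment: severity slows optimization when negative.
#' @param feedback_mos_on_hfpsi Effect of lagged MOS (per 10 units) on the
#'   latent severity transition: therapy improves severity when negative.
#' @param censor_beta_distance Log-odds of censoring per 100 km of distance.
#' @param censor_base_logit Baseline per-interval log-odds of censoring.
#' @param mos0_mean,mos0_sd Baseline MOS distribution before clipping to
#'   the 0-100 score domain.
#' @param hfpsi0_probs Baseline marginal probabilities of HFPSI 1-4.
#' @param cci_probs Marginal probabilities of mild/moderate/severe CCI.
#' @param event_death_frac Fraction of composite events recorded as deaths
#'   (the composite endpoint ignores the split).
#' @param encounters_per_interval Poisson mean for per-interval encounter
#'   counts in the medication-level generator (at least one encounter is
#'   always emitted).
#' @param hfpsi_missing_rate Fraction of patients with a missing baseline
#'   HFPSI component in the medication-level tables (drives exclusions).
#' @param seed Integer RNG seed.
#' @return An object of class `truth_params` (a validated named list).
#' @export
truth_params <- function(n_patients,
                         n_intervals = 8L,
                         beta_mos_per10 = log(0.88),
                         beta_hfpsi = log(c(1.5, 1.65, 3.0)),
                         beta_cci = log(c(1.2, 2.5)),
                         beta_age_per10 = log(1.4),
                         baseline_hazard = 0.015,
                         titration_mean_pp = 3.3,
                         titration_sd_pp = 2,
                         noise_sd_pp = 6,
                         feedback_hfpsi_on_mos = -2.5,
                         feedback_mos_on_hfpsi = -0.05,
                         censor_beta_distance = 0.5,
                         censor_base_logit = qlogis(0.04),
                         mos0_mean = 56, mos0_sd = 21,
                         hfpsi0_probs = c(0.464, 0.230, 0.185, 0.121),
                         cci_probs = c(0.199, 0.210, 0.591),
                         event_death_frac = 0.3,
                         encounters_per_interval = 3,
                         hfpsi_missing_rate = 0.02,
                         seed = 1L) {
  p <- list(
    n_patients = as.integer(n_patients), n_intervals = as.integer(n_intervals),
    beta_mos_per10 = beta_mos_per10, beta_hfpsi = beta_hfpsi,
    beta_cci = beta_cci, beta_age_per10 = beta_age_per10,
    baseline_hazard = baseline_hazard,
    titration_mean_pp = titration_mean_pp, titration_sd_pp = titration_sd_pp,
    noise_sd_pp = noise_sd_pp,
    feedback_hfpsi_on_mos = feedback_hfpsi_on_mos,
    feedback_mos_on_hfpsi = feedback_mos_on_hfpsi,
    censor_beta_distance = censor_beta_distance,
    censor_base_logit = censor_base_logit,
    mos0_mean = mos0_mean, mos0_sd = mos0_sd,
    hfpsi0_probs = hfpsi0_probs, cci_probs = cci_probs,
    event_death_frac = event_death_frac,
    encounters_per_interval = encounters_per_interval,
    hfpsi_missing_rate = hfpsi_missing_rate,
    seed = as.integer(seed)
  )
  validate_truth_params(p)
  structure(p, class = "truth_params")
}

validate_truth_params <- function(p) {
  for (f in c("beta_mos_per10", "beta_age_per10", "baseline_hazard",
              "titration_mean_pp", "titration_sd_pp", "noise_sd_pp",
              "feedback_hfpsi_on_mos", "feedback_mos_on_hfpsi",
              "censor_beta_distance", "censor_base_logit",
              "mos0_mean", "mos0_sd", "event_death_frac",
              "encounters_per_interval", "hfpsi_missing_rate")) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]])) {
      abort(sprintf("truth_params field `%s` must be a single finite number.", f))
    }
  }
  for (f in c("beta_hfpsi", "beta_cci", "hfpsi0_probs", "cci_probs")) {
    if (!is.numeric(p[[f]]) || any(!is.finite(p[[f]]))) {
      abort(sprintf("truth_params field `%s` must be finite numeric.", f))
    }
  }
  if (length(p$beta_hfpsi) != 3) abort("truth_params field `beta_hfpsi` must have length 3 (levels 2-4 vs 1).")
  if (length(p$beta_cci) != 2) abort("truth_params field `beta_cci` must have length 2 (moderate/severe vs mild).")
  if (p$n_patients < 1) abort("truth_params field `n_patients` must be positive.")
  if (p$n_intervals < 2) abort("truth_params field `n_intervals` must be >= 2.")
  if (p$baseline_hazard <= 0) abort("truth_params field `baseline_hazard` must be > 0.")
  if (p$titration_sd_pp < 0) abort("truth_params field `titration_sd_pp` must be >= 0.")
  if (length(p$hfpsi0_probs) != 4 || abs(sum(p$hfpsi0_probs) - 1) > 1e-6) {
    abort("truth_params field `hfpsi0_probs` must be 4 probabilities summing to 1.")
  }
  if (length(p$cci_probs) != 3 || abs(sum(p$cci_probs) - 1) > 1e-6) {
    abort("truth_params field `cci_probs` must be 3 probabilities summing to 1.")
  }
  invisible(p)
}

INTERVAL_DAYS <- 182L

# one step of the latent severity transition: ordinal 1-4 with logistic
# perturbation, shifted by lagged MOS (feedback_mos_on_hfpsi * MOS/10)
step_hfpsi <- function(hfpsi_prev, mos_prev, params, shock) {
  z <- hfpsi_prev + shock + params$feedback_mos_on_hfpsi * mos_prev / 10
  as.integer(clip(round(z), 1, 4))
}

# one step of the titration update (before clipping to the score domain)
step_mos <- function(mos_prev, hfpsi_prev, slope_i, params, noise) {
  clip(mos_prev + params$titration_mean_pp + slope_i +
         params$feedback_hfpsi_on_mos * (hfpsi_prev - 1) + noise, 0, 100)
}

interval_log_hazard <- function(mos, hfpsi, cci_cat, age, params) {
  log(params$baseline_hazard) +
    params$beta_mos_per10 * mos / 10 +
    c(0, params$beta_hfpsi)[hfpsi] +
    c(0, params$beta_cci)[as.integer(cci_cat)] +
    params$beta_age_per10 * age / 10
}

draw_baseline <- function(params) {
  n <- params$n_patients
  tibble(
    id = seq_len(n),
    age = rnorm_trunc(n, 64.7, 14.3, 20, 95),
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.65, 0.35)),
    race = sample(c("White", "African American", "Other"), n, replace = TRUE,
                  prob = c(0.755, 0.19, 0.055)),
    ethnicity = sample(c("Non-Hispanic", "Hispanic"), n, replace = TRUE,
                       prob = c(0.976, 0.024)),
    distance_km = stats::rgamma(n, shape = 2, scale = 40),
    cci_cat = factor(sample(c("MILD", "MODERATE", "SEVERE"), n, replace = TRUE,
                            prob = params$cci_probs),
                     levels = c("MILD", "MODERATE", "SEVERE")),
    hfpsi = sample.int(4L, n, replace = TRUE, prob = params$hfpsi0_probs),
    mos = clip(rnorm(n, params$mos0_mean, params$mos0_sd), 0, 100),
    slope_i = rnorm(n, 0, params$titration_sd_pp)
  )
}

#' Generate a score-level synthetic panel
#'
#' Simulates, per patient and 6-month interval, the interval-mean MOS, the
#' ordinal HFPSI severity state, and event/censoring outcomes, under the
#' data-generating process described in [truth_params()]:
#' * MOS follows a clipped random-slope titration process in which lagged
#'   severity slows optimization (`feedback_hfpsi_on_mos`);
#' * HFPSI evolves by an ordinal transition shifted by lagged MOS
#'   (`feedback_mos_on_hfpsi`), creating treatment-confounder feedback;
#' * the composite event is drawn from a per-interval discrete hazard
#'   `baseline_hazard * exp(beta_mos_per10 * MOS/10 + beta_hfpsi[HFPSI] +
#'   beta_cci[CCI] + beta_age_per10 * age/10)`, with the event day uniform
#'   within the interval;
#' * censoring is drawn from a logistic model with a distance term.
#'
#' Records after event or censoring are absent; every patient's final row
#' carries exactly one of the `event`/`censored` flags (administrative
#' censoring closes follow-up at the last interval).
#'
#' @param params A [truth_params()] object.
#' @return A list of class `mos_sim` with elements `panel` (tibble, one row
#'   per patient-interval at risk: `id`, `interval`, `start`, `stop`, `mos`,
#'   `prior_mos`, `hfpsi`, `hfpsi_lag1`, `cci_cat`, baseline covariates,
#'   `event`, `censored`) and `params` (the truth echo).
#' @export
generate_score_panel <- function(params) {
  stopifnot(inherits(params, "truth_params"))
  with_seed(params$seed, generate_score_panel_impl(params))
}

generate_score_panel_impl <- function(params) {
  K <- params$n_intervals
  base <- draw_baseline(params)
  state <- base |>
    mutate(prior_mos = NA_real_, hfpsi_lag1 = NA_integer_)
  rows <- vector("list", K)
  for (k in seq_len(K) - 1L) {
    n_at_risk <- nrow(state)
    if (n_at_risk == 0) break
    if (k > 0) {
      noise <- rnorm(n_at_risk, 0, params$noise_sd_pp)
      shock <- rlogis(n_at_risk, 0, 0.4)
      new_mos <- step_mos(state$mos, state$hfpsi, state$slope_i, params, noise)
      new_hfpsi <- step_hfpsi(state$hfpsi, state$mos, params, shock)
      state <- state |>
        mutate(prior_mos = .data$mos, hfpsi_lag1 = .data$hfpsi,
               mos = new_mos, hfpsi = new_hfpsi)
    }
    p_event <- 1 - exp(-exp(interval_log_hazard(
      state$mos, state$hfpsi, state$cci_cat, state$age, params)))
    ev <- runif(n_at_risk) < p_event
    ev_day <- ceiling(runif(n_at_risk) * INTERVAL_DAYS)
    p_cens <- plogis(params$censor_base_logit +
                       params$censor_beta_distance * state$distance_km / 100)
    cens <- !ev & (runif(n_at_risk) < p_cens)
    cens_day <- ceiling(runif(n_at_risk) * INTERVAL_DAYS)
    last_interval <- k == K - 1L
    cens <- cens | (!ev & last_interval)
    stop_day <- ifelse(ev, k * INTERVAL_DAYS + ev_day,
                       ifelse(cens & !last_interval, k * INTERVAL_DAYS + cens_day,
                              (k + 1L) * INTERVAL_DAYS))
    rows[[k + 1L]] <- state |>
      transmute(.data$id, interval = k, start = k * INTERVAL_DAYS,
                stop = stop_day, .data$mos, .data$prior_mos, .data$hfpsi,
                .data$hfpsi_lag1, .data$cci_cat, .data$age, .data$sex,
                .data$race, .data$ethnicity, .data$distance_km,
                event = ev, censored = cens)
    state <- state[!ev & !cens, ]
  }
  panel <- list_rbind(rows) |> arrange(.data$id, .data$interval)
  structure(list(panel = panel, params = params), class = "mos_sim")
}

#' Simulate pure linear-mixed-model score trajectories
#'
#' A dedicated, unclipped generator for validating the trend model:
#' `mos = beta0 + beta1 * time + b0_i + b1_i * time + e`, with
#' `(b0_i, b1_i)` bivariate normal. Defaults mirror the cohort conditions
#' (intercept 61 pp, slope 3.3 pp per 6-month interval). Values are not
#' clipped to the score range, so the fitted mixed model is exactly
#' well-specified.
#'
#' @param n_patients Number of patients.
#' @param n_intervals Observations per patient (time 0..n_intervals-1).
#' @param beta0,beta1 Fixed intercept (pp) and slope (pp per interval).
#' @param sd_intercept,sd_slope Random-effect SDs.
#' @param cor_is Intercept-slope correlation.
#' @param sd_resid Residual SD.
#' @param seed RNG seed.
#' @return Tibble with columns `id`, `time`, `mos`.
#' @export
simulate_lmm_data <- function(n_patients, n_intervals = 6, beta0 = 61,
                              beta1 = 3.3, sd_intercept = 18, sd_slope = 2,
                              cor_is = 0, sd_resid = 6, seed = 1L) {
  with_seed(seed, {
    b0 <- rnorm(n_patients, 0, sd_intercept)
    b1 <- rnorm(n_patients,
                if (sd_intercept > 0) cor_is * sd_slope / sd_intercept * b0 else 0,
                sd_slope * sqrt(max(0, 1 - cor_is^2)))
    tidyr::expand_grid(id = seq_len(n_patients), time = seq_len(n_intervals) - 1) |>
      mutate(mos = beta0 + beta1 * .data$time + b0[.data$id] +
               b1[.data$id] * .data$time + rnorm(dplyr::n(), 0, sd_resid))
  })
}
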