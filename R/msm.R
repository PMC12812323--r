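#' Specification of the MSM weight models
#'
#' The treatment (exposure-density) numerator model conditions on prior MOS,
#' baseline covariates and time; the denominator model additionally
#' conditions on the one-interval-lagged time-varying confounders (HFPSI,
#' CCI), so the denominator term set strictly contains the numerator's. The
#' censoring models share the structure, with baseline distance from the
#' treating center added to both censoring models. Time enters as a
#' categorical interval indicator.
#'
#' @param numerator Term names of the treatment numerator model.
#' @param denominator_extra Extra terms for the denominator model
#'   (time-varying confounders, lagged one interval).
#' @param censor_extra Extra terms for both censoring models.
#' @param truncation Lower/upper percentile truncation bounds for the
#'   weights (default 1st and 99th).
#' @return A validated list of class `msm_spec`.
#' @export
weight_model_spec <- function(numerator = c("prior_mos", "age", "sex", "race",
                                            "ethnicity", "interval_f"),
                              denominator_extra = c("hfpsi_lag1_f", "cci_cat"),
                              censor_extra = "distance_km",
                              truncation = c(0.01, 0.99)) {
  if (length(denominator_extra) == 0) {
    warn("Denominator adds no time-varying confounders; IPTW will be identically 1.")
  }
  if (any(denominator_extra %in% numerator)) {
    abort("Denominator extras must not repeat numerator terms.")
  }
  if (length(truncation) != 2 || truncation[1] >= truncation[2] ||
      truncation[1] <= 0 || truncation[2] >= 1) {
    abort("Truncation percentiles must satisfy 0 < low < high < 1.")
  }
  structure(list(numerator = numerator, denominator_extra = denominator_extra,
                 censor_extra = censor_extra, truncation = truncation),
            class = "msm_spec")
}

# add the derived factor columns the weight models use
prepare_weight_data <- function(panel) {
  panel |>
    mutate(
      interval_f = factor(.data$interval),
      hfpsi_lag1_f = factor(.data$hfpsi_lag1, levels = 1:4),
      prior_mos = .data$prior_mos
    )
}

# keep only terms that actually vary in `data` (degenerate columns carry no
# information and would break the linear fits)
varying_terms <- function(data, terms) {
  keep <- purrr::map_lgl(terms, function(t) {
    v <- data[[t]]
    !is.null(v) && n_distinct(v[!is.na(v)]) > 1
  })
  terms[keep]
}

build_formula <- function(response, terms, data) {
  terms <- varying_terms(data, terms)
  if (length(terms) == 0) terms <- "1"
  as.formula(paste(response, "~", paste(terms, collapse = " + ")))
}

#' Fit the exposure conditional-density models
#'
#' Two linear-Gaussian regressions of the current interval-mean MOS: the
#' numerator on prior MOS, baseline covariates and time; the denominator
#' additionally on the lagged time-varying confounders. The conditional
#' density at a row is the Normal density at the observed MOS with the
#' fitted mean and the model's (homoscedastic) residual SD. Only rows with
#' a defined prior MOS (interval >= 1) enter; interval 0 receives weight 1
#' downstream.
#'
#' @param panel Analysis panel (see [build_analysis_panel()] or
#'   [generate_score_panel()]).
#' @param spec A [weight_model_spec()].
#' @return List of class `msm_density_models` with elements `numerator` and
#'   `denominator`, each `list(fit, sigma)`.
#' @export
fit_exposure_density_models <- function(panel, spec = weight_model_spec()) {
  d <- prepare_weight_data(as_tibble(panel)) |> filter(!is.na(.data$prior_mos))
  if (nrow(d) == 0) abort("No rows with defined prior MOS (need intervals >= 1).")
  f_num <- build_formula("mos", spec$numerator, d)
  f_den <- build_formula("mos", c(spec$numerator, spec$denominator_extra), d)
  num <- lm(f_num, data = d)
  den <- lm(f_den, data = d)
  s_num <- sigma(num); s_den <- sigma(den)
  if (!is.finite(s_num) || s_num <= 0 || !is.finite(s_den) || s_den <= 0) {
    abort("Degenerate exposure model: residual SD must be positive.")
  }
  structure(list(numerator = list(fit = num, sigma = s_num),
                 denominator = list(fit = den, sigma = s_den)),
            class = "msm_density_models")
}

density_at <- function(model, newdata) {
  mu <- predict(model$fit, newdata = newdata)
  dnorm(newdata$mos, mean = mu, sd = model$sigma)
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' Per row (interval >= 1), the contribution is the numerator conditional
#' density over the denominator conditional density at the observed MOS;
#' the cumulative stabilized weight at interval k is the product of
#' contributions over intervals 1..k. Interval 0 has weight 1.
#'
#' @inheritParams fit_exposure_density_models
#' @param models Fitted [fit_exposure_density_models()] output.
#' @return Tibble `id`, `interval`, `iptw_contrib`, `iptw_cum`.
#' @export
compute_iptw <- function(panel, models) {
  d <- prepare_weight_data(as_tibble(panel))
  has_prior <- !is.na(d$prior_mos)
  contrib <- rep(1, nrow(d))
  if (any(has_prior)) {
    dn <- density_at(models$denominator, d[has_prior, ])
    if (any(dn <= 0 | !is.finite(dn))) {
      bad <- which(has_prior)[which(dn <= 0 | !is.finite(dn))[1]]
      abort(sprintf("Zero denominator density at row %d (id %s, interval %d).",
                    bad, d$id[bad], d$interval[bad]))
    }
    contrib[has_prior] <- density_at(models$numerator, d[has_prior, ]) / dn
  }
  d |>
    mutate(iptw_contrib = contrib) |>
    group_by(.data$id) |>
    arrange(.data$interval, .by_group = TRUE) |>
    mutate(iptw_cum = cumprod(.data$iptw_contrib)) |>
    ungroup() |>
    select("id", "interval", "iptw_contrib", "iptw_cum")
}

#' Fit the pooled-logistic censoring models
#'
#' Models the probability of remaining uncensored (not lost to follow-up)
#' in each interval. Administrative end-of-study censoring is deterministic
#' and is not modelled: the censoring indicator is loss to follow-up before
#' the administrative horizon. The numerator conditions on prior MOS (the
#' baseline MOS at interval 0), baseline covariates, time and baseline
#' distance; the denominator adds the lagged time-varying confounders.
#'
#' @inheritParams fit_exposure_density_models
#' @param horizon Administrative end of follow-up in days (default: the
#'   largest `stop` in the panel).
#' @return List of class `msm_censor_models` with `numerator`,
#'   `denominator` (binomial `glm`s) and `any_censoring` flag.
#' @export
fit_censoring_models <- function(panel, spec = weight_model_spec(),
                                 horizon = NULL) {
  d <- prepare_weight_data(as_tibble(panel))
  horizon <- horizon %||% max(d$stop)
  d <- d |>
    mutate(pm = dplyr::coalesce(.data$prior_mos, .data$mos),
           uncensored = as.integer(!(.data$censored & .data$stop < horizon)))
  if (all(d$uncensored == 1)) {
    warn("No loss-to-follow-up censoring; all IPCW set to 1.")
    return(structure(list(numerator = NULL, denominator = NULL,
                          any_censoring = FALSE, horizon = horizon),
                     class = "msm_censor_models"))
  }
  num_terms <- c("pm", setdiff(spec$numerator, "prior_mos"), spec$censor_extra)
  den_terms <- c(num_terms, spec$denominator_extra)
  # lagged confounders are undefined at interval 0; use the baseline state
  d <- d |>
    mutate(hfpsi_lag1_f = factor(dplyr::coalesce(.data$hfpsi_lag1, .data$hfpsi),
                                 levels = 1:4))
  # sparse strata (an interval with no loss to follow-up) produce fitted
  # probabilities of 1 and a separation warning; the resulting ratio is ~1
  # and the percentile truncation guards the tails, so these are expected
  num <- suppressWarnings(
    glm(build_formula("uncensored", num_terms, d), data = d, family = binomial()))
  den <- suppressWarnings(
    glm(build_formula("uncensored", den_terms, d), data = d, family = binomial()))
  structure(list(numerator = num, denominator = den, any_censoring = TRUE,
                 horizon = horizon),
            class = "msm_censor_models")
}

#' Stabilized inverse-probability-of-censoring weights
#'
#' @inheritParams fit_censoring_models
#' @param models Fitted [fit_censoring_models()] output.
#' @return Tibble `id`, `interval`, `ipcw_contrib`, `ipcw_cum`.
#' @export
compute_ipcw <- function(panel, models) {
  d <- prepare_weight_data(as_tibble(panel)) |>
    mutate(pm = dplyr::coalesce(.data$prior_mos, .data$mos),
           hfpsi_lag1_f = factor(dplyr::coalesce(.data$hfpsi_lag1, .data$hfpsi),
                                 levels = 1:4))
  if (!models$any_censoring) {
    contrib <- rep(1, nrow(d))
  } else {
    p_num <- predict(models$numerator, newdata = d, type = "response")
    p_den <- predict(models$denominator, newdata = d, type = "response")
    if (any(p_den <= 0)) abort("Zero denominator censoring probability.")
    contrib <- p_num / p_den
  }
  d |>
    mutate(ipcw_contrib = contrib) |>
    group_by(.data$id) |>
    arrange(.data$interval, .by_group = TRUE) |>
    mutate(ipcw_cum = cumprod(.data$ipcw_contrib)) |>
    ungroup() |>
    select("id", "interval", "ipcw_contrib", "ipcw_cum")
}

#' Percentile-truncate and combine IPTW and IPCW
#'
#' Each cumulative weight vector is winsorized at its own empirical
#' truncation percentiles (pooled over all rows), then the truncated
#' weights are multiplied row-wise.
#'
#' @param iptw,ipcw Numeric vectors of cumulative stabilized weights,
#'   aligned to the same rows.
#' @param truncation Percentile pair, default `c(0.01, 0.99)`.
#' @return Tibble `iptw_trunc`, `ipcw_trunc`, `weight`.
#' @export
truncate_and_combine <- function(iptw, ipcw, truncation = c(0.01, 0.99)) {
  wins <- function(w) {
    q <- quantile(w, truncation, names = FALSE)
    clip(w, q[1], q[2])
  }
  ti <- wins(iptw); tc <- wins(ipcw)
  tibble(iptw_trunc = ti, ipcw_trunc = tc, weight = ti * tc)
}

#' Build the full stabilized weight table
#'
#' Fits the exposure-density and censoring models, computes cumulative
#' stabilized IPTW and IPCW, truncates each at the spec's percentiles and
#' combines them row-wise.
#'
#' @inheritParams fit_exposure_density_models
#' @return Tibble of class `msm_weights`: `id`, `interval`,
#'   `iptw_contrib`, `ipcw_contrib`, `iptw_cum`, `ipcw_cum`, `iptw_trunc`,
#'   `ipcw_trunc`, `weight`; the fitted models are attached as attributes.
#' @export
build_msm_weights <- function(panel, spec = weight_model_spec()) {
  dens <- fit_exposure_density_models(panel, spec)
  cens <- fit_censoring_models(panel, spec)
  iptw <- compute_iptw(panel, dens)
  ipcw <- compute_ipcw(panel, cens)
  w <- iptw |>
    left_join(ipcw, by = c("id", "interval")) |>
    bind_cols(truncate_and_combine(iptw$iptw_cum, ipcw$ipcw_cum, spec$truncation))
  attr(w, "density_models") <- dens
  attr(w, "censor_models") <- cens
  class(w) <- c("msm_weights", class(w))
  w
}

#' Fit the marginal structural Cox model (model D)
#'
#' Weighted Cox partial likelihood over the counting-process rows with the
#' current-interval MOS per 10 units as the exposure, using the combined
#' truncated stabilized weights and patient-clustered robust standard
#' errors. Because the stabilized numerator conditions on the baseline
#' covariates, the weighted outcome model adjusts for them as well (a
#' requirement of stabilized weighting: the weights only remove
#' time-varying confounding within baseline-covariate strata).
#'
#' @inheritParams fit_exposure_density_models
#' @param weights A [build_msm_weights()] table (computed from `panel` if
#'   omitted).
#' @param baseline_covariates Baseline covariate terms included in the
#'   weighted outcome model; must correspond to the weight numerator's
#'   baseline terms. `age10` is derived from `age` if absent.
#' @return An `hfmos_cox` fit.
#' @export
fit_msm <- function(panel, weights = NULL, spec = weight_model_spec(),
                    baseline_covariates = c("age10", "sex", "race", "ethnicity")) {
  panel <- as_tibble(panel)
  if (is.null(weights)) weights <- build_msm_weights(panel, spec)
  d <- panel |>
    left_join(weights[, c("id", "interval", "weight")], by = c("id", "interval")) |>
    mutate(mos10 = .data$mos / 10)
  if (!"age10" %in% names(d) && "age" %in% names(d)) d$age10 <- d$age / 10
  if (any(d$weight <= 0 | !is.finite(d$weight))) abort("Weights must be positive and finite.")
  covs <- varying_terms(d, intersect(baseline_covariates, names(d)))
  f <- as.formula(paste("~", paste(c("mos10", covs), collapse = " + ")))
  fit_cox(d, f, cluster = "id", weights = "weight")
}
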