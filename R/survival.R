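#' Kaplan-Meier curves per group
#'
#' Product-limit estimator with Greenwood variance and log-log confidence
#' intervals; the cumulative event probability (1 - survival) is what the
#' tertile figure plots.
#'
#' @param data Tibble with columns `time`, `event` (logical/0-1), and
#'   optionally `group`.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble of class `hfmos_km`: `group`, `time`, `n_risk`,
#'   `n_event`, `surv`, `cum_event`, `lower`, `upper` (CI on survival).
#' @export
km_estimate <- function(data, conf_level = 0.95) {
  data <- as_tibble(data)
  if (!"group" %in% names(data)) data$group <- "all"
  empty <- data |> count(.data$group) |> filter(.data$n == 0)
  if (nrow(empty)) warn("Omitting group(s) with zero subjects.")
  fit <- survival::survfit(
    survival::Surv(time, event) ~ group,
    data = data |> mutate(event = as.integer(.data$event)),
    conf.type = "log-log", conf.int = conf_level
  )
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep("all", length(s$time)) else {
    sub("^group=", "", as.character(s$strata))
  }
  out <- tibble(
    group = grp, time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    surv = s$surv, cum_event = 1 - s$surv,
    lower = s$lower, upper = s$upper
  )
  class(out) <- c("hfmos_km", class(out))
  out
}

#' Log-rank test across groups
#'
#' @inheritParams km_estimate
#' @return Tibble with `statistic` (chi-square), `df`, `p_value`.
#' @export
logrank_test <- function(data) {
  data <- as_tibble(data)
  if (!"group" %in% names(data) || n_distinct(data$group) < 2) {
    abort("Log-rank test needs at least two groups.")
  }
  sd <- survival::survdiff(
    survival::Surv(time, event) ~ group,
    data = data |> mutate(event = as.integer(.data$event))
  )
  df <- length(sd$n) - 1
  tibble(statistic = sd$chisq, df = df,
         p_value = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Event rate per 100 person-years
#'
#' @param events Number of events.
#' @param person_years Total person-years at risk (> 0).
#' @return `100 * events / person_years`.
#' @export
#' @examples
#' event_rate_per_100py(582, 1496) # 38.9 per 100 person-years
event_rate_per_100py <- function(events, person_years) {
  if (any(person_years <= 0)) abort("Person-years must be > 0.")
  100 * events / person_years
}

#' Fit a Cox proportional hazards model
#'
#' Thin, typed wrapper around [survival::coxph()] with Efron tie handling,
#' optional patient-clustered robust (sandwich) standard errors, and tidy
#' output with hazard ratios and normal-approximation confidence intervals
#' on the log-HR scale.
#'
#' @param data Model data (single-spell with `time`/`event`, or
#'   counting-process with `start`/`stop`/`event`).
#' @param formula Right-hand-side formula of covariates, e.g. `~ mos10 + age10`.
#' @param cluster Optional column name (string) for clustered robust SEs.
#' @param weights Optional column name (string) of case weights.
#' @param ties Tie handling, `"efron"` (default) or `"breslow"`. Breslow
#'   makes integer case weights exactly equivalent to row duplication.
#' @param conf_level Confidence level.
#' @return Object of class `hfmos_cox`: list with the `coxph` fit, a `tidy`
#'   tibble (`term`, `estimate` = log-HR, `hr`, `se`, `robust_se`,
#'   `conf_low`, `conf_high`, `p_value`), `n`, `n_events`, `loglik`.
#' @export
fit_cox <- function(data, formula, cluster = NULL, weights = NULL,
                    ties = c("efron", "breslow"), conf_level = 0.95) {
  ties <- match.arg(ties)
  data <- as_tibble(data)
  lhs <- if (all(c("start", "stop") %in% names(data))) {
    "survival::Surv(start, stop, event)"
  } else "survival::Surv(time, event)"
  rhs <- paste(deparse(formula[[2]]), collapse = " ")
  f <- as.formula(paste(lhs, "~", rhs))
  data$event <- as.integer(data$event)
  if (sum(data$event) < 1) abort("Cox fit needs at least one event.")

  args <- list(formula = f, data = data, ties = ties, x = TRUE, model = TRUE)
  if (!is.null(cluster)) args$cluster <- data[[cluster]]
  if (!is.null(weights)) args$weights <- data[[weights]]
  fit <- do.call(survival::coxph, args)
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info))) {
    abort("Cox partial-likelihood maximization did not converge.")
  }

  sm <- summary(fit, conf.int = conf_level)
  co <- sm$coefficients
  use_robust <- "robust se" %in% colnames(co)
  se_used <- if (use_robust) co[, "robust se"] else co[, "se(coef)"]
  z <- qnorm(1 - (1 - conf_level) / 2)
  td <- tibble(
    term = rownames(co),
    estimate = co[, "coef"],
    hr = exp(co[, "coef"]),
    se = co[, "se(coef)"],
    robust_se = if (use_robust) co[, "robust se"] else NA_real_,
    conf_low = exp(co[, "coef"] - z * se_used),
    conf_high = exp(co[, "coef"] + z * se_used),
    p_value = co[, ncol(co)]
  )
  structure(
    list(fit = fit, tidy = td, n = sm$n, n_events = sm$nevent,
         loglik = fit$loglik[length(fit$loglik)],
         robust = use_robust, conf_level = conf_level),
    class = "hfmos_cox"
  )
}

#' @export
print.hfmos_cox <- function(x, ...) {
  cat(sprintf("Cox fit: %d rows, %d events%s\n", x$n, x$n_events,
              if (x$robust) " (cluster-robust SE)" else ""))
  print(x$tidy)
  invisible(x)
}

#' Fit the study's Cox model A, B or C on an analysis panel
#'
#' Model A: unadjusted baseline MOS per 10 units (single spell per patient).
#' Model B: A plus age per 10 years, sex, race, ethnicity, HFPSI (reference
#' level 1) and CCI category (reference mild). Model C: counting-process
#' time-varying fit with the one-interval-lagged cumulative MOS per 10 units
#' plus the baseline covariates, with patient-clustered robust SEs.
#'
#' @param panel Panel from [build_analysis_panel()] (or the score-level
#'   generator), with columns `mos`, `lagcum_mos`, `start`, `stop`, `event`,
#'   `age`, `sex`, `race`, `ethnicity`, `hfpsi` (baseline), `cci_cat`.
#' @param model `"A"`, `"B"` or `"C"`.
#' @return An `hfmos_cox` fit.
#' @export
fit_cox_model <- function(panel, model = c("A", "B", "C")) {
  model <- match.arg(model)
  panel <- as_tibble(panel)
  covs <- "age10 + sex + race + ethnicity + hfpsi_base + cci_cat"
  if (model %in% c("A", "B")) {
    base <- panel |>
      group_by(.data$id) |>
      summarise(
        mos10 = first(.data$mos[.data$interval == 0]) / 10,
        time = max(.data$stop), event = any(.data$event),
        age10 = first(.data$age) / 10, sex = first(.data$sex),
        race = first(.data$race), ethnicity = first(.data$ethnicity),
        hfpsi_base = factor(first(.data$hfpsi[.data$interval == 0])),
        cci_cat = first(.data$cci_cat), .groups = "drop"
      )
    f <- if (model == "A") ~mos10 else as.formula(paste("~ mos10 +", covs))
    fit_cox(base, f)
  } else {
    cp <- panel |>
      group_by(.data$id) |>
      mutate(
        # score-level panels carry no encounter-level history; the lagged
        # cumulative exposure is then the running mean of prior interval means
        lagcum_mos = if ("lagcum_mos" %in% names(panel)) .data$lagcum_mos else {
          dplyr::coalesce(dplyr::lag(cummean(.data$mos)), .data$mos)
        },
        lagcum10 = .data$lagcum_mos / 10,
        age10 = .data$age / 10,
        hfpsi_base = factor(first(.data$hfpsi[.data$interval == 0]))
      ) |>
      ungroup()
    fit_cox(cp, as.formula(paste("~ lagcum10 +", covs)),
            cluster = "id")
  }
}

#' Schoenfeld-residual proportional-hazards check
#'
#' Scaled Schoenfeld residuals regressed on event time via
#' [survival::cox.zph()].
#'
#' @param cox An `hfmos_cox` fit.
#' @return Tibble with `term` (including `"GLOBAL"`), `chisq`, `df`, `p_value`.
#' @export
schoenfeld_ph_test <- function(cox) {
  stopifnot(inherits(cox, "hfmos_cox"))
  if (cox$n_events < 2) abort("Schoenfeld test needs at least 2 events.")
  zp <- survival::cox.zph(cox$fit)
  tb <- zp$table
  tibble(term = rownames(tb), chisq = tb[, "chisq"], df = tb[, "df"],
         p_value = tb[, "p"])
}
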