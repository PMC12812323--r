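#' Assign encounters to 6-month intervals
#'
#' Interval `k = floor(days since index / 182)` with half-open day bins
#' `[182k, 182(k+1))`; the index-date encounter is interval 0 (baseline).
#' Encounters beyond the configured maximum interval are dropped with a
#' message.
#'
#' @param day Integer vector of days since the index date (>= 0).
#' @param interval_days Interval width in days (default 182).
#' @param max_interval Largest retained interval index (default 7).
#' @return Integer interval index, `NA` for dropped encounters.
#' @export
assign_intervals <- function(day, interval_days = INTERVAL_DAYS, max_interval = 7L) {
  if (any(day < 0)) abort("Encounters before the index date are not allowed.")
  k <- as.integer(floor(day / interval_days))
  dropped <- k > max_interval
  if (any(dropped)) {
    inform(sprintf("Dropping %d encounter(s) beyond interval %d.",
                   sum(dropped), max_interval))
    k[dropped] <- NA_integer_
  }
  k
}

#' Per patient-interval mean MOS
#'
#' Arithmetic mean of encounter-level MOS within each patient-interval.
#' Intervals with no encounter (up to each patient's last observed interval)
#' carry the previous interval's mean forward.
#'
#' @param scored Tibble with columns `id`, `interval`, `mos`.
#' @return Tibble `id`, `interval`, `mos` (one row per patient-interval,
#'   contiguous from 0 to the patient's last observed interval).
#' @export
interval_mean_mos <- function(scored) {
  means <- scored |>
    filter(!is.na(.data$interval), !is.na(.data$mos)) |>
    group_by(.data$id, .data$interval) |>
    summarise(mos = mean(.data$mos), .groups = "drop")
  means |>
    group_by(.data$id) |>
    tidyr::complete(interval = seq(0L, max(.data$interval))) |>
    tidyr::fill("mos", .direction = "down") |>
    ungroup() |>
    arrange(.data$id, .data$interval)
}

#' One-interval-lagged cumulative mean MOS
#'
#' For interval `k >= 1` the exposure is the mean of all *encounter-level*
#' MOS values observed strictly before the interval's start day
#' (`182k`); interval 0 has no prior observations and uses the baseline MOS
#' itself. Intervals with no prior encounters (possible only at `k = 0`)
#' carry the last available cumulative value forward.
#'
#' @param scored Tibble with columns `id`, `day`, `mos` (encounter level).
#' @param panel Tibble with columns `id`, `interval` (e.g. from
#'   [interval_mean_mos()]).
#' @param interval_days Interval width in days.
#' @return `panel` with an added `lagcum_mos` column.
#' @export
lagged_cumulative_mos <- function(scored, panel, interval_days = INTERVAL_DAYS) {
  scored <- scored |> filter(!is.na(.data$mos))
  panel |>
    mutate(lagcum_mos = purrr::map2_dbl(.data$id, .data$interval, function(i, k) {
      prior <- scored$mos[scored$id == i & scored$day < k * interval_days]
      if (length(prior)) mean(prior) else NA_real_
    })) |>
    group_by(.data$id) |>
    mutate(lagcum_mos = ifelse(.data$interval == 0 & is.na(.data$lagcum_mos),
                               .data$mos, .data$lagcum_mos)) |>
    tidyr::fill("lagcum_mos", .direction = "down") |>
    ungroup()
}

#' Baseline MOS tertiles
#'
#' Cuts a baseline score vector at its empirical 33rd and 67th percentiles
#' (linear-interpolation quantile definition). Ties at a cut point go to the
#' lower tertile.
#'
#' @param x Numeric vector of baseline scores (n >= 3).
#' @return A list with `tertile` (factor `T1` < `T2` < `T3`) and `cuts`
#'   (the two percentile values). A degenerate (constant) input yields all
#'   `T1` with a warning.
#' @export
assign_tertiles <- function(x) {
  if (length(x) < 3) abort("Need at least 3 values to form tertiles.")
  cuts <- quantile(x, c(0.33, 0.67), names = FALSE, na.rm = TRUE)
  if (cuts[1] == cuts[2] && diff(range(x, na.rm = TRUE)) == 0) {
    warn("Degenerate score distribution: all values equal; assigning all to T1.")
    return(list(tertile = factor(rep("T1", length(x)), levels = c("T1", "T2", "T3")),
                cuts = cuts))
  }
  lab <- dplyr::case_when(x <= cuts[1] ~ "T1", x <= cuts[2] ~ "T2", TRUE ~ "T3")
  list(tertile = factor(lab, levels = c("T1", "T2", "T3")), cuts = cuts)
}

#' Counting-process rows from an interval panel and outcomes
#'
#' Expands each patient's follow-up into half-open rows
#' `[182k, min(182(k+1), T))` where `T` is the day of first event or
#' censoring, with the event flag on the terminal row only. Total risk time
#' equals follow-up to the first event or censoring; person-years are risk
#' days / 365.25.
#'
#' @param outcomes Tibble with one row per patient: `id`, `day` (event or
#'   censor day since index, > 0), `event` (logical).
#' @param interval_days,max_interval Interval structure.
#' @return Tibble `id`, `interval`, `start`, `stop`, `event`, `censored`.
#' @export
build_counting_process <- function(outcomes, interval_days = INTERVAL_DAYS,
                                   max_interval = 7L) {
  outcomes <- as_tibble(outcomes)
  if (nrow(outcomes) == 0) abort("Outcomes table is empty.")
  if (any(outcomes$day <= 0)) abort("Event/censor day must be after the index date.")
  horizon <- (max_interval + 1L) * interval_days
  outcomes |>
    mutate(truncated = .data$day > horizon,
           day = pmin(.data$day, horizon),
           event = .data$event & !.data$truncated) |>
    rowwise() |>
    mutate(rows = list({
      d <- .data$day
      ks <- seq(0L, (ceiling(d / interval_days) - 1L))
      tibble(interval = ks, start = ks * interval_days,
             stop = pmin((ks + 1L) * interval_days, d))
    })) |>
    ungroup() |>
    select("id", "event", "rows") |>
    tidyr::unnest("rows") |>
    group_by(.data$id) |>
    mutate(terminal = .data$interval == max(.data$interval),
           censored = .data$terminal & !.data$event,
           event = .data$terminal & .data$event) |>
    ungroup() |>
    select("id", "interval", "start", "stop", "event", "censored")
}

#' Build the full analysis panel from scored encounters
#'
#' Orchestrates interval binning, per-interval mean MOS with carry-forward,
#' the one-interval-lagged cumulative exposure, baseline tertiles, and
#' counting-process rows, joined to baseline covariates and time-varying
#' risk indices.
#'
#' @param scored Encounter-level tibble: `id`, `day` (days since index),
#'   `mos`, and optionally `hfpsi`.
#' @param outcomes One row per patient: `id`, `day`, `event` (logical).
#' @param baseline One row per patient: `id` plus baseline covariates
#'   (e.g. `age`, `sex`, `race`, `ethnicity`, `cci_cat`, `distance_km`,
#'   baseline `hfpsi`).
#' @param interval_days,max_interval Interval structure.
#' @return A tibble with one row per patient-interval at risk: exposure
#'   columns `mos` (interval mean), `prior_mos`, `lagcum_mos`, lagged
#'   `hfpsi_lag1` (if `hfpsi` supplied), counting-process `start`, `stop`,
#'   `event`, `censored`, baseline covariates, and `tertile`.
#' @export
build_analysis_panel <- function(scored, outcomes, baseline,
                                 interval_days = INTERVAL_DAYS,
                                 max_interval = 7L) {
  scored <- as_tibble(scored) |>
    mutate(interval = assign_intervals(.data$day, interval_days, max_interval)) |>
    filter(!is.na(.data$interval))

  cp <- build_counting_process(outcomes, interval_days, max_interval)
  means <- interval_mean_mos(scored)
  means <- lagged_cumulative_mos(scored, means, interval_days)

  panel <- cp |>
    left_join(means, by = c("id", "interval")) |>
    group_by(.data$id) |>
    tidyr::fill("mos", "lagcum_mos", .direction = "down") |>
    mutate(prior_mos = lag(.data$mos)) |>
    ungroup()

  if ("hfpsi" %in% names(scored)) {
    hf <- scored |>
      filter(!is.na(.data$hfpsi)) |>
      group_by(.data$id, .data$interval) |>
      summarise(hfpsi = .data$hfpsi[which.max(.data$day)], .groups = "drop")
    panel <- panel |>
      left_join(hf, by = c("id", "interval")) |>
      group_by(.data$id) |>
      tidyr::fill("hfpsi", .direction = "down") |>
      mutate(hfpsi_lag1 = lag(.data$hfpsi)) |>
      ungroup()
  }

  base <- as_tibble(baseline)
  b0 <- base |>
    left_join(panel |> filter(.data$interval == 0) |> select("id", mos0 = "mos"),
              by = "id")
  tert <- assign_tertiles(b0$mos0)
  b0$tertile <- tert$tertile
  out <- panel |> left_join(b0, by = "id")
  attr(out, "tertile_cuts") <- tert$cuts
  out
}
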