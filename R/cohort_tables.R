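# Default drug used per class when the generator inverts a target MOS into
# a concrete regimen.
DEFAULT_SIM_DRUGS <- c(RASI = "lisinopril", BETA_BLOCKER = "metoprolol-succinate",
                       MRA = "spironolactone", SGLT2I = "dapagliflozin")

#' Invert a target MOS into a concrete regimen
#'
#' Chooses per-class dose fractions that sum to `4 * target / 100` by
#' filling classes to target in a fixed order (RASI, beta-blocker, MRA,
#' SGLT2 inhibitor) and giving the first unfilled class the remaining
#' fraction, so that [compute_mos()] on the emitted orders reproduces the
#' target score (all classes eligible).
#'
#' @param target_mos Target score in `[0, 100]`.
#' @param formulary Formulary tibble.
#' @param drugs Named character vector: drug used per class.
#' @return Tibble of orders (`drug`, `daily_dose_mg`), doses 0 for absent
#'   classes.
#' @export
invert_mos <- function(target_mos, formulary = default_formulary(),
                       drugs = DEFAULT_SIM_DRUGS) {
  stopifnot(target_mos >= 0, target_mos <= 100)
  m <- 4 * target_mos / 100
  fractions <- numeric(4)
  for (i in 1:4) {
    fractions[i] <- clip(m, 0, 1)
    m <- m - fractions[i]
  }
  targets <- formulary$target_daily_mg[match(drugs[GDMT_CLASSES], formulary$drug)]
  tibble(drug = unname(drugs[GDMT_CLASSES]),
         daily_dose_mg = round(fractions * targets, 3))
}

#' Generate medication-level synthetic cohort tables
#'
#' The high-fidelity companion of [generate_score_panel()]: the same latent
#' MOS/severity/outcome trajectories are drawn (same seed, same draws), and
#' then realised as EHR-like tables - patients, encounters with vitals and
#' labs drawn around typical ambulatory HFrEF values (SBP 121 +/- 17.3,
#' SCr 1.33 +/- 0.94, K+ 4.4 +/- 0.45), medication orders constructed by
#' inverting the MOS formula so the scoring engine reproduces the latent
#' trajectory, Charlson condition sets consistent with the drawn severity
#' grade, and an outcomes table. Vitals are truncated to eligibility-safe
#' ranges so no contraindication or escalation rule fires on synthetic
#' encounters; the generator emulates dose titration, not contraindication
#' dynamics.
#'
#' @param params A [truth_params()] object.
#' @param formulary Formulary used to construct regimens.
#' @return A list of class `mos_cohort` with elements `patients`,
#'   `encounters`, `medications`, `conditions`, `intolerances`, `outcomes`
#'   (tibbles), `latent` (the score-level panel) and `params`.
#' @export
generate_cohort_tables <- function(params, formulary = default_formulary()) {
  stopifnot(inherits(params, "truth_params"))
  if (nrow(formulary) == 0) abort("Formulary must be nonempty.")
  sim <- generate_score_panel(params)
  with_seed(params$seed + 1000003L,
            realise_cohort_tables(sim, params, formulary))
}

realise_cohort_tables <- function(sim, params, formulary) {
  panel <- sim$panel
  index_date <- as.Date("2021-07-01")
  base <- panel |> group_by(.data$id) |> slice_min(.data$interval, n = 1) |> ungroup()

  n <- nrow(base)
  patients <- base |>
    transmute(.data$id, age = round(.data$age, 1), .data$sex, .data$race,
              .data$ethnicity, distance_km = round(.data$distance_km, 1),
              index_date = index_date,
              diabetes = runif(n) < 0.35,
              af_flutter = runif(n) < 0.30,
              recent_hosp = runif(n) < 0.25)

  # encounters: >= 1 per at-risk interval, first encounter at the index date
  enc <- panel |>
    mutate(n_enc = 1L + rpois(dplyr::n(), max(params$encounters_per_interval - 1, 0))) |>
    rowwise() |>
    mutate(days = list({
      pool <- seq(.data$start, max(.data$start, .data$stop - 1L))
      d <- sort(pool[sample.int(length(pool), min(.data$n_enc, length(pool)))])
      if (.data$interval == 0L) d[1] <- 0L
      unique(d)
    })) |>
    ungroup() |>
    select("id", "interval", "mos", "hfpsi", "days") |>
    tidyr::unnest_longer("days", values_to = "day") |>
    distinct(.data$id, .data$day, .keep_all = TRUE)

  m <- nrow(enc)
  encounters <- enc |>
    mutate(
      date = index_date + .data$day,
      sbp = round(rnorm_trunc(m, 121, 17.3, 100, 200), 0),
      dbp = round(rnorm_trunc(m, 68.8, 12.1, 45, 110), 0),
      pulse = round(rnorm_trunc(m, 76.5, 13.8, 62, 130), 0),
      scr = round(rnorm_trunc(m, 1.33, 0.94, 0.4, 4), 2),
      k = round(rnorm_trunc(m, 4.4, 0.45, 3.2, 4.9), 1),
      egfr = round(rnorm_trunc(m, 63, 23, 32, 120), 0),
      bun = round(rlnorm(m, log(12 + 5 * .data$hfpsi), 0.25), 0),
      bnp = round(rlnorm(m, log(150) + 0.7 * .data$hfpsi, 0.5), 0),
      nyha = as.integer(clip(round(.data$hfpsi + rnorm(m, 0, 0.6)), 1, 4)),
      lvef = round(rnorm_trunc(m, 28.9, 8.1, 10, 40), 0)
    )

  # missing-HFPSI patients: baseline BNP not recorded
  miss_ids <- patients$id[runif(n) < params$hfpsi_missing_rate]
  encounters <- encounters |>
    mutate(bnp = ifelse(.data$id %in% miss_ids & .data$day == 0, NA_real_, .data$bnp))

  # medication orders: full current regimen re-stated at every encounter
  # (zero-dose rows discontinue a drug for carry-forward scoring); classes
  # fill to target in canonical order so per-class fractions sum to the
  # target score (the vectorized equivalent of invert_mos())
  sim_targets <- formulary$target_daily_mg[match(DEFAULT_SIM_DRUGS[GDMT_CLASSES],
                                                 formulary$drug)]
  medications <- tidyr::crossing(
    encounters |> select("id", "date", "mos"),
    tibble(slot = 1:4, drug = unname(DEFAULT_SIM_DRUGS[GDMT_CLASSES]),
           target = sim_targets)
  ) |>
    mutate(fraction = clip(4 * .data$mos / 100 - (.data$slot - 1), 0, 1),
           daily_dose_mg = round(.data$fraction * .data$target, 3)) |>
    select("id", "date", "drug", "daily_dose_mg")

  conditions <- draw_conditions(base$id, base$cci_cat)

  intolerances <- tibble(id = integer(), class = character())

  last <- panel |> group_by(.data$id) |> slice_max(.data$interval, n = 1) |> ungroup()
  outcomes <- last |>
    transmute(.data$id, date = index_date + .data$stop,
              type = ifelse(.data$event,
                            ifelse(runif(dplyr::n()) < params$event_death_frac,
                                   "death", "hospitalization"),
                            "censored"))

  encounters <- encounters |>
    select("id", "date", "sbp", "dbp", "pulse", "scr", "k", "egfr", "bun",
           "bnp", "nyha", "lvef")

  structure(
    list(patients = patients, encounters = encounters,
         medications = medications, conditions = conditions,
         intolerances = intolerances, outcomes = outcomes,
         latent = panel, params = params),
    class = "mos_cohort"
  )
}

draw_conditions <- function(ids, cci_cat) {
  w1_pool <- c("myocardial_infarction", "peripheral_vascular_disease",
               "cerebrovascular_disease", "chronic_pulmonary_disease",
               "peptic_ulcer_disease", "diabetes_uncomplicated")
  sets <- purrr::map2(ids, as.character(cci_cat), function(i, cat) {
    # everyone carries the heart-failure diagnosis (weight 1)
    conds <- "congestive_heart_failure"
    extra <- switch(cat,
      MILD = sample(w1_pool, sample(0:1, 1)),
      MODERATE = c("renal_disease", sample(w1_pool, sample(0:1, 1))),
      SEVERE = c("metastatic_solid_tumor", sample(w1_pool, sample(0:2, 1)))
    )
    tibble(id = i, condition = unique(c(conds, extra)))
  })
  list_rbind(sets)
}

#' Apply the cohort inclusion filters
#'
#' Removes, in order, (1) patients fully optimized at baseline
#' (baseline MOS = 100) and (2) patients with any missing HFPSI component at
#' baseline, returning the exclusion counts per reason in application order.
#'
#' @param cohort A `mos_cohort` from [generate_cohort_tables()], or a plain
#'   list with the same table elements.
#' @param formulary,rules Scoring configuration for the baseline MOS.
#' @param map HFPSI scoring map.
#' @return A list with `tables` (the filtered cohort tables), `exclusions`
#'   (tibble `reason`, `n` in application order), `n_retained`, and
#'   `baseline` (per-retained-patient baseline score and indices).
#' @export
apply_cohort_filters <- function(cohort, formulary = default_formulary(),
                                 rules = default_eligibility_rules(),
                                 map = read_hfpsi_map()) {
  pts <- as_tibble(cohort$patients)
  enc <- as_tibble(cohort$encounters)
  base_enc <- enc |>
    group_by(.data$id) |>
    slice_min(.data$date, n = 1, with_ties = FALSE) |>
    ungroup()
  base_scores <- score_encounters(base_enc, cohort$medications,
                                  cohort$intolerances, formulary, rules)

  fully_opt <- base_scores$id[!base_scores$mos_undefined &
                                base_scores$mos >= 100 - 1e-9]
  remaining <- setdiff(pts$id, fully_opt)

  comp <- base_enc |>
    filter(.data$id %in% remaining) |>
    left_join(pts[, c("id", "diabetes", "af_flutter", "recent_hosp")], by = "id")
  comp$hfpsi <- compute_hfpsi(comp$bun, comp$bnp, comp$nyha, comp$diabetes,
                              comp$af_flutter, comp$recent_hosp, map)
  missing_hfpsi <- comp$id[is.na(comp$hfpsi)]
  retained <- setdiff(remaining, missing_hfpsi)

  keep <- function(tbl) as_tibble(tbl) |> filter(.data$id %in% retained)
  tables <- list(
    patients = keep(pts), encounters = keep(enc),
    medications = keep(cohort$medications), conditions = keep(cohort$conditions),
    intolerances = keep(cohort$intolerances), outcomes = keep(cohort$outcomes)
  )
  baseline <- base_scores |>
    filter(.data$id %in% retained) |>
    left_join(comp[, c("id", "hfpsi")], by = "id")

  list(
    tables = tables,
    exclusions = tibble(reason = c("fully_optimized", "missing_hfpsi"),
                        n = c(length(fully_opt), length(missing_hfpsi))),
    n_retained = length(retained),
    baseline = baseline
  )
}

#' Write cohort tables as CSV plus a truth.json
#'
#' One comma-separated UTF-8 file per table (ISO-8601 dates) and the
#' generator's ground-truth parameters serialized alongside for downstream
#' recovery tests.
#'
#' @param cohort A `mos_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_cohort_tables <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("patients", "encounters", "medications", "conditions",
              "intolerances", "outcomes")
  paths <- character()
  for (t in tables) {
    p <- file.path(dir, paste0(t, ".csv"))
    write.csv(cohort[[t]], p, row.names = FALSE, fileEncoding = "UTF-8")
    paths <- c(paths, p)
  }
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(unclass(cohort$params), tp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, tp))
}
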