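#' Build a patient-encounter snapshot for scoring
#'
#' The scoring engine works on one patient encounter at a time: the current
#' medication regimen (drug and total daily dose), the vitals and labs that
#' gate eligibility, NYHA class, and any documented GDMT class intolerances.
#'
#' @param orders Data frame with columns `drug` and `daily_dose_mg` (total
#'   daily dose). May have zero rows.
#' @param sbp,pulse Systolic blood pressure (mmHg) and pulse (bpm).
#' @param k Serum potassium (mmol/L).
#' @param egfr Estimated glomerular filtration rate (mL/min/1.73m2).
#' @param scr Serum creatinine (mg/dL).
#' @param nyha NYHA class 1-4.
#' @param intolerant Character vector of GDMT classes with documented
#'   intolerance or allergy.
#' @param id,date Optional identifiers carried through to results.
#' @param age,sex,race,ethnicity Optional demographics (stored, not used by
#'   any default scoring rule).
#' @return An object of class `mos_snapshot`.
#' @export
patient_snapshot <- function(orders = NULL, sbp = NA_real_, pulse = NA_real_,
                             k = NA_real_, egfr = NA_real_, scr = NA_real_,
                             nyha = NA_integer_, intolerant = character(),
                             id = NA_character_, date = NA,
                             age = NA_real_, sex = NA_character_,
                             race = NA_character_, ethnicity = NA_character_) {
  orders <- if (is.null(orders) || nrow(as.data.frame(orders)) == 0) {
    tibble(drug = character(), daily_dose_mg = numeric())
  } else {
    as_tibble(orders)[, c("drug", "daily_dose_mg")]
  }
  if (any(orders$daily_dose_mg < 0)) abort("Daily doses must be >= 0.")
  if (anyDuplicated(orders$drug)) {
    # later orders supersede earlier ones for the same drug on the same date
    orders <- orders |> group_by(.data$drug) |> slice_tail(n = 1) |> ungroup()
  }
  if (!is.na(nyha) && !nyha %in% 1:4) abort("NYHA class must be in 1..4.")
  bad <- setdiff(intolerant, GDMT_CLASSES)
  if (length(bad)) abort(sprintf("Unknown intolerant class: %s", paste(bad, collapse = ", ")))
  structure(
    list(id = id, date = date, orders = orders, sbp = sbp, pulse = pulse,
         k = k, egfr = egfr, scr = scr, nyha = nyha,
         intolerant = unique(intolerant), age = age, sex = sex,
         race = race, ethnicity = ethnicity),
    class = "mos_snapshot"
  )
}

#' Classify a medication regimen against the formulary
#'
#' Maps each order to its GDMT class and computes the dose fraction
#' `min(daily dose / target daily dose, 1)`. Within a class, the order with
#' the highest fraction is retained (no summing across drugs or RASI
#' subtypes). Drugs absent from the formulary are ignored as non-GDMT, with
#' a message.
#'
#' @param orders Data frame with columns `drug`, `daily_dose_mg`.
#' @param formulary A formulary tibble from [read_formulary()].
#' @return A tibble with one row per GDMT class (all four classes always
#'   present): `class`, `drug`, `subtype`, `daily_dose_mg`, `fraction`.
#'   Classes with no order have `fraction` 0 and `drug` `NA`. The attribute
#'   `subtype_fractions` records the best fraction per RASI subtype, which
#'   the comparator scores use (e.g. "any ARNI dose").
#' @export
classify_regimen <- function(orders, formulary = default_formulary()) {
  orders <- as_tibble(orders)
  matched <- orders |>
    inner_join(formulary, by = "drug") |>
    mutate(fraction = pmin(.data$daily_dose_mg / .data$target_daily_mg, 1))
  unknown <- setdiff(orders$drug, formulary$drug)
  if (length(unknown)) {
    inform(sprintf("Ignoring non-GDMT order(s): %s", paste(unknown, collapse = ", ")))
  }
  rasi <- matched |> filter(.data$class == "RASI", .data$daily_dose_mg > 0)
  if (n_distinct(rasi$subtype) > 1) {
    warn("Multiple RASI subtypes prescribed simultaneously; scoring the highest-fraction subtype only.")
  }
  best <- matched |>
    group_by(.data$class) |>
    arrange(desc(.data$fraction), .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    select("class", "drug", "subtype", "daily_dose_mg", "fraction")
  out <- tibble(class = GDMT_CLASSES) |>
    left_join(best, by = "class") |>
    mutate(
      fraction = replace_na(.data$fraction, 0),
      daily_dose_mg = replace_na(.data$daily_dose_mg, 0)
    )
  sub_fr <- rasi |>
    group_by(.data$subtype) |>
    summarise(fraction = max(c(0, .data$fraction)), .groups = "drop")
  attr(out, "subtype_fractions") <- sub_fr
  out
}

rule_fires <- function(snapshot, rule) {
  val <- snapshot[[rule$var]]
  if (is.null(val) || is.na(val)) return(NA) # missing data: rule cannot fire
  if (rule$op == "lt") val < rule$value else val > rule$value
}

#' Assess a patient's eligibility for one GDMT class
#'
#' Statuses, in order of precedence: `INTOLERANT` (documented intolerance or
#' allergy), `CONTRAINDICATED` (an initiation-blocking rule fires),
#' `ESCALATION_BLOCKED` (class prescribed below target and an up-titration
#' rule fires), else `ELIGIBLE`. Missing vitals/labs are handled
#' conservatively: a rule that cannot be evaluated does not fire, and the
#' result carries a missing-data annotation.
#'
#' @param snapshot A [patient_snapshot()].
#' @param gdmt_class One of `"RASI"`, `"BETA_BLOCKER"`, `"MRA"`, `"SGLT2I"`.
#' @param rules Rule set from [read_eligibility_rules()].
#' @param fraction Current dose fraction of the class (used to decide
#'   whether an escalation block applies).
#' @return A list with `status`, `reasons` (character), and
#'   `missing_data` (logical).
#' @export
assess_eligibility <- function(snapshot, gdmt_class,
                               rules = default_eligibility_rules(),
                               fraction = 0) {
  stopifnot(gdmt_class %in% GDMT_CLASSES)
  if (gdmt_class %in% snapshot$intolerant) {
    return(list(status = "INTOLERANT", reasons = "documented intolerance/allergy",
                missing_data = FALSE))
  }
  missing_any <- FALSE
  fired <- character()
  for (r in rules$contraindication[[gdmt_class]] %||% list()) {
    hit <- rule_fires(snapshot, r)
    if (is.na(hit)) missing_any <- TRUE else if (hit) fired <- c(fired, r$reason %||% r$var)
  }
  if (length(fired)) {
    return(list(status = "CONTRAINDICATED", reasons = fired, missing_data = missing_any))
  }
  if (fraction > 0 && fraction < 1) {
    for (r in rules$escalation_block[[gdmt_class]] %||% list()) {
      hit <- rule_fires(snapshot, r)
      if (is.na(hit)) missing_any <- TRUE else if (hit) fired <- c(fired, r$reason %||% r$var)
    }
    if (length(fired)) {
      return(list(status = "ESCALATION_BLOCKED", reasons = fired, missing_data = missing_any))
    }
  }
  list(status = "ELIGIBLE", reasons = character(), missing_data = missing_any)
}

next_titration_step <- function(drug, daily_dose_mg, formulary) {
  row <- formulary[formulary$drug == drug, ]
  if (nrow(row) == 0) return(NA_real_)
  steps <- row$steps[[1]]
  higher <- steps[steps > daily_dose_mg + 1e-9]
  if (length(higher)) higher[1] else NA_real_
}

#' Compute the Medication Optimization Score for one encounter
#'
#' The MOS is a percentage from 0 (least optimized) to 100 (most optimized).
#' Each of the four GDMT classes contributes one possible point, earned in
#' proportion to the prescribed fraction of the guideline target daily dose.
#' Classes with a documented intolerance or a firing contraindication rule
#' are removed from both numerator and denominator, so the score is never
#' deflated (or inflated) by medication the patient cannot receive. A class
#' prescribed below target whose up-titration is blocked by vitals earns
#' full credit at its current dose. Per-class recommendations (INITIATE /
#' TITRATE to the next formulary step / CONTINUE / NONE) are returned
#' alongside. The HFC (0-7), modified HFC (0-8, also rescaled to 0-100) and
#' KCMO (0-100) comparator scores are computed from the same regimen.
#'
#' @param snapshot A [patient_snapshot()].
#' @inheritParams classify_regimen
#' @param rules Rule set from [read_eligibility_rules()].
#' @return An object of class `mos_score`: a list with `mos` (percent, `NA`
#'   with `undefined = TRUE` if all four classes are excluded),
#'   `assessments` (tibble of per-class status, points, recommendation),
#'   `hfc`, `mhfc_points`, `mhfc_scaled`, `kcmo`, and `undefined`.
#' @export
#' @examples
#' snap <- patient_snapshot(
#'   orders = data.frame(drug = c("lisinopril", "carvedilol"),
#'                       daily_dose_mg = c(20, 50)),
#'   sbp = 120, pulse = 75, k = 4.2, egfr = 65
#' )
#' compute_mos(snap)
compute_mos <- function(snapshot, formulary = default_formulary(),
                        rules = default_eligibility_rules()) {
  stopifnot(inherits(snapshot, "mos_snapshot"))
  cls <- classify_regimen(snapshot$orders, formulary)
  elig <- purrr::map(seq_len(nrow(cls)), function(i) {
    assess_eligibility(snapshot, cls$class[i], rules, fraction = cls$fraction[i])
  })
  cls$status <- map_chr(elig, "status")
  cls$reason <- map_chr(elig, function(e) paste(e$reasons, collapse = "; "))
  cls$missing_data <- purrr::map_lgl(elig, "missing_data")

  excluded <- cls$status %in% c("INTOLERANT", "CONTRAINDICATED")
  cls$points_possible <- ifelse(excluded, 0, 1)
  cls$points_earned <- dplyr::case_when(
    excluded ~ 0,
    cls$status == "ESCALATION_BLOCKED" & cls$fraction > 0 ~ 1, # not penalized
    TRUE ~ cls$fraction
  )
  cls$recommendation <- dplyr::case_when(
    excluded ~ "NONE",
    cls$status == "ELIGIBLE" & cls$fraction == 0 ~ "INITIATE",
    cls$status == "ELIGIBLE" & cls$fraction < 1 ~ "TITRATE",
    TRUE ~ "CONTINUE"
  )
  cls$next_dose_mg <- ifelse(
    cls$recommendation == "TITRATE",
    map_dbl(seq_len(nrow(cls)),
            function(i) next_titration_step(cls$drug[i], cls$daily_dose_mg[i], formulary)),
    NA_real_
  )

  denom <- sum(cls$points_possible)
  undefined <- denom == 0
  mos <- if (undefined) NA_real_ else 100 * sum(cls$points_earned) / denom

  contra <- cls$class[excluded]
  hfc <- compute_hfc(cls, contraindicated = contra)
  mhfc <- compute_mhfc(cls, contraindicated = contra)
  kcmo <- compute_kcmo(cls, statuses = setNames(cls$status, cls$class))

  structure(
    list(mos = mos, assessments = cls, hfc = hfc,
         mhfc_points = mhfc$points, mhfc_scaled = mhfc$scaled,
         kcmo = kcmo, undefined = undefined,
         id = snapshot$id, date = snapshot$date),
    class = "mos_score"
  )
}

#' @export
print.mos_score <- function(x, ...) {
  cat(sprintf("MOS: %s   HFC: %d   mHFC: %d (%.1f)   KCMO: %s\n",
              if (x$undefined) "undefined (all classes excluded)" else sprintf("%.1f%%", x$mos),
              x$hfc, x$mhfc_points, x$mhfc_scaled,
              if (is.na(x$kcmo)) "undefined" else sprintf("%.1f", x$kcmo)))
  print(x$assessments[, c("class", "drug", "fraction", "status", "recommendation")])
  invisible(x)
}

rasi_subtype_fraction <- function(classification, subtypes) {
  sf <- attr(classification, "subtype_fractions")
  if (is.null(sf) || nrow(sf) == 0) return(0)
  hit <- sf$fraction[sf$subtype %in% subtypes]
  if (length(hit)) max(hit) else 0
}

#' Heart Failure Collaboratory (HFC) score
#'
#' Point scheme over beta-blocker, RASI and MRA slots (no SGLT2i; range
#' 0-7): beta-blockers and ACEI/ARB earn 0 for no treatment, 1 below 50% of
#' target, 2 at or above 50%; an MRA earns 2 for any dose; an ARNI earns 3
#' for any dose and supersedes ACEI/ARB in the RASI slot. A contraindicated
#' class is treated as guideline-adherent and earns its slot maximum (RASI
#' slot maximum taken as 3).
#'
#' @param classification Output of [classify_regimen()].
#' @param contraindicated Character vector of classes treated as
#'   contraindicated (intolerance counts too).
#' @return Integer in 0..7.
#' @export
compute_hfc <- function(classification, contraindicated = character()) {
  fr <- setNames(classification$fraction, classification$class)
  half <- function(f) if (f >= 0.5) 2L else if (f > 0) 1L else 0L
  bb <- if ("BETA_BLOCKER" %in% contraindicated) 2L else half(fr[["BETA_BLOCKER"]])
  mra <- if ("MRA" %in% contraindicated) 2L else if (fr[["MRA"]] > 0) 2L else 0L
  arni_fr <- rasi_subtype_fraction(classification, "ARNI")
  acei_arb_fr <- rasi_subtype_fraction(classification, c("ACEI", "ARB"))
  rasi <- if ("RASI" %in% contraindicated) 3L
          else if (arni_fr > 0) 3L
          else half(acei_arb_fr)
  as.integer(bb + mra + rasi)
}

#' Modified HFC (mHFC) score
#'
#' As [compute_hfc()] but every slot uses the 0/1/2 scheme at the 50%
#' threshold (including the MRA), and an ARNI is scored as two components:
#' sacubitril and valsartan each earn 0/1/2 against their component targets,
#' so target-dose sacubitril/valsartan alone yields 4 of the 8 possible
#' points. The scaled score is points / 8 x 100. A contraindicated class
#' earns its slot maximum (RASI slot maximum 4).
#'
#' @inheritParams compute_hfc
#' @return A list with integer `points` (0..8) and `scaled` (0..100).
#' @export
compute_mhfc <- function(classification, contraindicated = character()) {
  fr <- setNames(classification$fraction, classification$class)
  half <- function(f) if (f >= 0.5) 2L else if (f > 0) 1L else 0L
  bb <- if ("BETA_BLOCKER" %in% contraindicated) 2L else half(fr[["BETA_BLOCKER"]])
  mra <- if ("MRA" %in% contraindicated) 2L else half(fr[["MRA"]])
  arni_fr <- rasi_subtype_fraction(classification, "ARNI")
  acei_arb_fr <- rasi_subtype_fraction(classification, c("ACEI", "ARB"))
  rasi <- if ("RASI" %in% contraindicated) 4L
  else if (arni_fr > 0) {
    # fixed-ratio combination: each component sits at the same fraction of
    # its own target as the combination does of the total
    half(arni_fr) + half(arni_fr)
  } else half(acei_arb_fr)
  points <- as.integer(bb + mra + rasi)
  list(points = points, scaled = points / 8 * 100)
}

#' Kansas City Medical Optimization (KCMO) score
#'
#' Mean over eligible GDMT classes of the prescribed-to-target daily dose
#' proportion (capped at 1), with the MRA contributing 1 if any dose is
#' prescribed and 0 otherwise, reported on a 0-100 scale. Intolerant and
#' contraindicated classes are excluded from the average.
#'
#' @inheritParams compute_hfc
#' @param statuses Named character vector of per-class eligibility statuses.
#' @return Numeric 0-100, or `NA` if no class is eligible.
#' @export
compute_kcmo <- function(classification, statuses) {
  keep <- !statuses[classification$class] %in% c("INTOLERANT", "CONTRAINDICATED")
  if (!any(keep)) return(NA_real_)
  contrib <- ifelse(classification$class == "MRA",
                    as.numeric(classification$fraction > 0),
                    classification$fraction)
  mean(contrib[keep]) * 100
}

#' Score a batch of encounters
#'
#' Joins medication orders to encounters by patient id and date, builds a
#' snapshot per encounter, and scores each with [compute_mos()].
#'
#' @param encounters Tibble with columns `id`, `date`, and the vitals/labs
#'   `sbp`, `pulse`, `k`, `egfr` (optionally `scr`, `nyha`).
#' @param medications Tibble with columns `id`, `date`, `drug`,
#'   `daily_dose_mg`. Orders are carried forward: the regimen at an
#'   encounter is the latest order per drug on or before the encounter date.
#' @param intolerances Optional tibble with columns `id`, `class`.
#' @inheritParams compute_mos
#' @return A tibble with one row per encounter: identifiers, `mos`, `hfc`,
#'   `mhfc_points`, `mhfc_scaled`, `kcmo`, `mos_undefined`, and per-class
#'   recommendation columns `rec_<class>`.
#' @export
score_encounters <- function(encounters, medications,
                             intolerances = NULL,
                             formulary = default_formulary(),
                             rules = default_eligibility_rules()) {
  encounters <- as_tibble(encounters)
  medications <- as_tibble(medications)
  vitals <- c("sbp", "pulse", "k", "egfr", "scr")
  for (v in vitals) if (!v %in% names(encounters)) encounters[[v]] <- NA_real_

  unknown <- setdiff(unique(medications$drug), formulary$drug)
  if (length(unknown)) {
    inform(sprintf("Ignoring non-GDMT order(s): %s", paste(unknown, collapse = ", ")))
  }

  # regimen at each encounter: latest order per drug on or before the date
  med_enc <- medications |>
    inner_join(encounters |> select("id", enc_date = "date") |> distinct(),
               by = "id", relationship = "many-to-many") |>
    filter(.data$date <= .data$enc_date) |>
    group_by(.data$id, .data$enc_date, .data$drug) |>
    slice_max(.data$date, n = 1, with_ties = FALSE) |>
    ungroup() |>
    filter(.data$daily_dose_mg > 0) |>
    inner_join(formulary |> select("drug", "class", "subtype", "target_daily_mg"),
               by = "drug") |>
    mutate(fraction = pmin(.data$daily_dose_mg / .data$target_daily_mg, 1))

  multi_rasi <- med_enc |>
    filter(.data$class == "RASI") |>
    distinct(.data$id, .data$enc_date, .data$subtype) |>
    count(.data$id, .data$enc_date) |>
    filter(.data$n > 1)
  if (nrow(multi_rasi)) {
    warn(sprintf("%d encounter(s) with multiple RASI subtypes prescribed simultaneously; scoring the highest-fraction subtype only.",
                 nrow(multi_rasi)))
  }

  best <- med_enc |>
    group_by(.data$id, .data$enc_date, .data$class) |>
    slice_max(.data$fraction, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("id", "enc_date", "class", "drug", "subtype", "daily_dose_mg", "fraction")

  rasi_sub <- med_enc |>
    filter(.data$class == "RASI") |>
    group_by(.data$id, .data$enc_date) |>
    summarise(
      arni_fr = max(c(0, .data$fraction[.data$subtype == "ARNI"])),
      acei_arb_fr = max(c(0, .data$fraction[.data$subtype %in% c("ACEI", "ARB")])),
      .groups = "drop"
    )

  intol <- if (is.null(intolerances) || nrow(as.data.frame(intolerances)) == 0) {
    tibble(id = encounters$id[0], class = character())
  } else as_tibble(intolerances) |> distinct(.data$id, .data$class) |>
    mutate(intolerant = TRUE)

  grid <- tidyr::crossing(
    encounters |> select("id", "date", dplyr::all_of(vitals)) |> distinct(),
    class = GDMT_CLASSES
  ) |>
    left_join(best, by = c("id", "date" = "enc_date", "class")) |>
    mutate(fraction = replace_na(.data$fraction, 0),
           daily_dose_mg = replace_na(.data$daily_dose_mg, 0))
  if (nrow(intol) && "intolerant" %in% names(intol)) {
    grid <- grid |>
      left_join(intol, by = c("id", "class")) |>
      mutate(intolerant = replace_na(.data$intolerant, FALSE))
  } else {
    grid$intolerant <- FALSE
  }

  grid <- eligibility_status_vec(grid, rules)

  excluded <- grid$status %in% c("INTOLERANT", "CONTRAINDICATED")
  grid$points_possible <- as.numeric(!excluded)
  grid$points_earned <- dplyr::case_when(
    excluded ~ 0,
    grid$status == "ESCALATION_BLOCKED" & grid$fraction > 0 ~ 1,
    TRUE ~ grid$fraction
  )
  grid$recommendation <- dplyr::case_when(
    excluded ~ "NONE",
    grid$status == "ELIGIBLE" & grid$fraction == 0 ~ "INITIATE",
    grid$status == "ELIGIBLE" & grid$fraction < 1 ~ "TITRATE",
    TRUE ~ "CONTINUE"
  )

  wide <- grid |>
    select("id", "date", "class", "fraction", "status", "points_possible",
           "points_earned", "recommendation") |>
    pivot_wider(names_from = "class",
                values_from = c("fraction", "status", "points_possible",
                                "points_earned", "recommendation")) |>
    left_join(rasi_sub, by = c("id", "date" = "enc_date")) |>
    mutate(arni_fr = replace_na(.data$arni_fr, 0),
           acei_arb_fr = replace_na(.data$acei_arb_fr, 0))

  half2 <- function(f) ifelse(f >= 0.5, 2L, ifelse(f > 0, 1L, 0L))
  out <- wide |>
    mutate(
      denom = .data$points_possible_RASI + .data$points_possible_BETA_BLOCKER +
        .data$points_possible_MRA + .data$points_possible_SGLT2I,
      earned = .data$points_earned_RASI + .data$points_earned_BETA_BLOCKER +
        .data$points_earned_MRA + .data$points_earned_SGLT2I,
      mos_undefined = .data$denom == 0,
      mos = ifelse(.data$mos_undefined, NA_real_, 100 * .data$earned / .data$denom),
      contra_rasi = .data$status_RASI %in% c("INTOLERANT", "CONTRAINDICATED"),
      contra_bb = .data$status_BETA_BLOCKER %in% c("INTOLERANT", "CONTRAINDICATED"),
      contra_mra = .data$status_MRA %in% c("INTOLERANT", "CONTRAINDICATED"),
      contra_sglt = .data$status_SGLT2I %in% c("INTOLERANT", "CONTRAINDICATED"),
      hfc = as.integer(
        ifelse(.data$contra_bb, 2L, half2(.data$fraction_BETA_BLOCKER)) +
          ifelse(.data$contra_mra, 2L, ifelse(.data$fraction_MRA > 0, 2L, 0L)) +
          ifelse(.data$contra_rasi, 3L,
                 ifelse(.data$arni_fr > 0, 3L, half2(.data$acei_arb_fr)))),
      mhfc_points = as.integer(
        ifelse(.data$contra_bb, 2L, half2(.data$fraction_BETA_BLOCKER)) +
          ifelse(.data$contra_mra, 2L, half2(.data$fraction_MRA)) +
          ifelse(.data$contra_rasi, 4L,
                 ifelse(.data$arni_fr > 0, 2L * half2(.data$arni_fr),
                        half2(.data$acei_arb_fr)))),
      mhfc_scaled = .data$mhfc_points / 8 * 100,
      kcmo_n = (!.data$contra_rasi) + (!.data$contra_bb) + (!.data$contra_mra) +
        (!.data$contra_sglt),
      kcmo = ifelse(.data$kcmo_n == 0, NA_real_, 100 * (
        ifelse(.data$contra_rasi, 0, .data$fraction_RASI) +
          ifelse(.data$contra_bb, 0, .data$fraction_BETA_BLOCKER) +
          ifelse(.data$contra_mra, 0, as.numeric(.data$fraction_MRA > 0)) +
          ifelse(.data$contra_sglt, 0, .data$fraction_SGLT2I)) / .data$kcmo_n)
    ) |>
    select("id", "date", "mos", "mos_undefined", "hfc", "mhfc_points",
           "mhfc_scaled", "kcmo",
           rec_rasi = "recommendation_RASI",
           rec_beta_blocker = "recommendation_BETA_BLOCKER",
           rec_mra = "recommendation_MRA", rec_sglt2i = "recommendation_SGLT2I")
  encounters |> select("id", "date") |> left_join(out, by = c("id", "date"))
}

# vectorized eligibility over an encounter x class grid
eligibility_status_vec <- function(grid, rules) {
  n <- nrow(grid)
  contra <- logical(n); esc <- logical(n)
  eval_rule <- function(rows, r) {
    v <- grid[[r$var]][rows]
    fired <- if (r$op == "lt") v < r$value else v > r$value
    fired & !is.na(fired)
  }
  for (cls in GDMT_CLASSES) {
    rows <- which(grid$class == cls)
    for (r in rules$contraindication[[cls]] %||% list()) {
      contra[rows] <- contra[rows] | eval_rule(rows, r)
    }
    for (r in rules$escalation_block[[cls]] %||% list()) {
      esc[rows] <- esc[rows] | eval_rule(rows, r)
    }
  }
  grid$status <- dplyr::case_when(
    grid$intolerant ~ "INTOLERANT",
    contra ~ "CONTRAINDICATED",
    esc & grid$fraction > 0 & grid$fraction < 1 ~ "ESCALATION_BLOCKED",
    TRUE ~ "ELIGIBLE"
  )
  grid
}
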