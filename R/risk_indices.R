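#' Charlson condition dictionary
#'
#' Seventeen condition groups with the original Charlson weights, plus the
#' hierarchical pairs (e.g. diabetes with vs without complications) in which
#' only the higher-weighted member counts.
#'
#' @param path YAML dictionary path; defaults to the packaged one.
#' @return A list with `weights` (named numeric) and `hierarchy`
#'   (list of 2-vectors, lower member first).
#' @export
read_charlson_dictionary <- function(path = hfmos_extdata("charlson_weights.yaml")) {
  d <- yaml::read_yaml(path)
  list(weights = unlist(d$weights), hierarchy = d$hierarchy)
}

#' Charlson Comorbidity Index
#'
#' Sums the dictionary weights over the distinct condition groups present.
#' Unknown condition codes are ignored with a message; each group counts at
#' most once; for a hierarchical pair with both members present only the
#' higher-weighted member is counted.
#'
#' @param conditions Character vector of condition-group codes for one
#'   patient.
#' @param dictionary Dictionary from [read_charlson_dictionary()].
#' @return Integer score >= 0.
#' @export
#' @examples
#' compute_cci(c("diabetes_uncomplicated", "renal_disease")) # 3
compute_cci <- function(conditions, dictionary = read_charlson_dictionary()) {
  conditions <- unique(as.character(conditions))
  unknown <- setdiff(conditions, names(dictionary$weights))
  if (length(unknown)) {
    inform(sprintf("Ignoring unknown condition code(s): %s",
                   paste(unknown, collapse = ", ")))
    conditions <- setdiff(conditions, unknown)
  }
  for (pair in dictionary$hierarchy) {
    if (all(pair %in% conditions)) conditions <- setdiff(conditions, pair[1])
  }
  as.integer(sum(dictionary$weights[conditions]))
}

#' Categorize a Charlson score into severity grades
#'
#' Scores 1-2 are mild, 3-4 moderate, >= 5 severe. A score of 0 falls below
#' the published grade boundaries; it is binned with MILD and the result
#' carries a `"score_zero"` attribute listing the affected positions.
#'
#' @param score Integer vector of CCI scores (>= 0).
#' @return Factor with levels `MILD`, `MODERATE`, `SEVERE`.
#' @export
categorize_cci <- function(score) {
  if (any(score < 0)) abort("CCI scores must be >= 0.")
  out <- factor(
    dplyr::case_when(score <= 2 ~ "MILD", score <= 4 ~ "MODERATE", TRUE ~ "SEVERE"),
    levels = c("MILD", "MODERATE", "SEVERE")
  )
  if (any(score == 0)) attr(out, "score_zero") <- which(score == 0)
  out
}

#' Read an HFPSI scoring map
#'
#' @param path YAML map path; defaults to the packaged one.
#' @return A validated list of component breakpoints, points, and class cuts.
#' @export
read_hfpsi_map <- function(path = hfmos_extdata("hfpsi_map.yaml")) {
  m <- yaml::read_yaml(path)
  needed <- c("bun_breaks", "bnp_breaks", "nyha_ge3_points", "diabetes_points",
              "af_flutter_points", "recent_hosp_points", "class_cuts")
  if (!all(needed %in% names(m))) {
    abort(sprintf("HFPSI map missing field(s): %s",
                  paste(setdiff(needed, names(m)), collapse = ", ")))
  }
  for (f in c("bun_breaks", "bnp_breaks", "class_cuts")) {
    if (is.unsorted(m[[f]], strictly = TRUE)) {
      abort(sprintf("HFPSI map `%s` must be strictly increasing.", f))
    }
  }
  if (length(m$class_cuts) != 3) abort("HFPSI map needs exactly 3 class cuts.")
  m
}

#' Heart-failure patient severity index (ordinal 1-4)
#'
#' Scores six components (BUN, BNP, NYHA class, diabetes, AF/flutter
#' history, hospitalization within the prior 6 months) through a monotone
#' integer map and cuts the total onto severity classes 1 (lowest) to 4
#' (highest). Any missing component yields `NA` ("missing HFPSI", which
#' drives cohort exclusion upstream).
#'
#' @param bun Blood urea nitrogen, mg/dL.
#' @param bnp B-type natriuretic peptide, pg/mL.
#' @param nyha NYHA class 1-4.
#' @param diabetes,af_flutter,recent_hosp Logical component flags.
#' @param map Scoring map from [read_hfpsi_map()].
#' @return Integer vector in 1..4, `NA` where any component is missing.
#'   Vectorized over all components.
#' @export
compute_hfpsi <- function(bun, bnp, nyha, diabetes, af_flutter, recent_hosp,
                          map = read_hfpsi_map()) {
  n <- max(length(bun), length(bnp), length(nyha), length(diabetes),
           length(af_flutter), length(recent_hosp))
  comp <- tibble(
    bun = rep_len(as.numeric(bun), n), bnp = rep_len(as.numeric(bnp), n),
    nyha = rep_len(as.numeric(nyha), n),
    diabetes = rep_len(as.logical(diabetes), n),
    af_flutter = rep_len(as.logical(af_flutter), n),
    recent_hosp = rep_len(as.logical(recent_hosp), n)
  )
  total <- findInterval(comp$bun, map$bun_breaks) +
    findInterval(comp$bnp, map$bnp_breaks) +
    (comp$nyha >= 3) * map$nyha_ge3_points +
    comp$diabetes * map$diabetes_points +
    comp$af_flutter * map$af_flutter_points +
    comp$recent_hosp * map$recent_hosp_points
  cls <- findInterval(total, map$class_cuts) + 1L
  cls[!complete.cases(comp)] <- NA_integer_
  as.integer(cls)
}

#' Batch risk indices for a cohort
#'
#' @param conditions Tibble with columns `id`, `condition`.
#' @param components Tibble with one row per patient: `id`, `bun`, `bnp`,
#'   `nyha`, `diabetes`, `af_flutter`, `recent_hosp`.
#' @inheritParams compute_cci
#' @inheritParams compute_hfpsi
#' @return Tibble with `id`, `cci`, `cci_cat`, `hfpsi`.
#' @export
compute_risk_indices <- function(conditions, components,
                                 dictionary = read_charlson_dictionary(),
                                 map = read_hfpsi_map()) {
  cci_tbl <- as_tibble(components)["id"] |>
    distinct() |>
    mutate(cci = map_int(.data$id, function(i) {
      compute_cci(conditions$condition[conditions$id == i], dictionary)
    }))
  cci_tbl$cci_cat <- categorize_cci(cci_tbl$cci)
  comp <- as_tibble(components)
  comp$hfpsi <- compute_hfpsi(comp$bun, comp$bnp, comp$nyha, comp$diabetes,
                              comp$af_flutter, comp$recent_hosp, map)
  cci_tbl |> left_join(comp[, c("id", "hfpsi")], by = "id")
}
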