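#' Read a GDMT formulary
#'
#' A formulary maps drug names to one of the four scored GDMT classes
#' (RAS inhibitor, beta-blocker, MRA, SGLT2 inhibitor), with subtype
#' (ACEI/ARB/ARNI for the RASI class), a guideline target daily dose and an
#' ordered titration ladder. The packaged default carries standard guideline
#' target doses (e.g. sacubitril/valsartan 400 mg/day total, lisinopril
#' 40 mg, carvedilol 50 mg, spironolactone 25 mg, dapagliflozin 10 mg) and
#' is fully editable configuration.
#'
#' @param path Path to a formulary YAML file; defaults to the packaged one.
#' @return A tibble with one row per drug: `drug`, `class`, `subtype`,
#'   `target_daily_mg`, `steps` (list column of the titration ladder), and
#'   `components` (list column; non-`NULL` only for fixed-ratio combinations
#'   such as sacubitril/valsartan).
#' @export
#' @examples
#' read_formulary()
read_formulary <- function(path = hfmos_extdata("formulary.yaml")) {
  raw <- yaml::read_yaml(path)
  entries <- purrr::map(raw$drugs, function(d) {
    tibble(
      drug = d$drug,
      class = d$class,
      subtype = d$subtype %||% "none",
      target_daily_mg = as.numeric(d$target_daily_mg),
      steps = list(as.numeric(d$steps)),
      components = list(d$components)
    )
  }) |> list_rbind()
  validate_formulary(entries)
  entries
}

#' @rdname read_formulary
#' @export
default_formulary <- function() read_formulary()

validate_formulary <- function(f) {
  if (nrow(f) == 0) abort("Formulary is empty.")
  if (anyDuplicated(f$drug)) abort("Each drug must appear once in the formulary.")
  if (!all(f$class %in% GDMT_CLASSES)) {
    abort(sprintf("Unknown GDMT class in formulary: %s",
                  paste(setdiff(f$class, GDMT_CLASSES), collapse = ", ")))
  }
  if (any(f$target_daily_mg <= 0)) abort("Target daily doses must be > 0.")
  ok_steps <- purrr::map2_lgl(f$steps, f$target_daily_mg, function(s, t) {
    length(s) >= 1 && all(diff(s) > 0) && isTRUE(all.equal(s[length(s)], t))
  })
  if (!all(ok_steps)) {
    abort("Titration steps must be strictly increasing and end at the target dose.")
  }
  invisible(f)
}

#' Read eligibility rules for MOS scoring
#'
#' Rules come in two kinds: `contraindication` rules block a class entirely
#' (the class leaves both numerator and denominator of the MOS), and
#' `escalation_block` rules block up-titration of an already-prescribed
#' class (the current dose then earns full credit, so patients are not
#' penalized for clinical ineligibility to escalate). Each rule is a strict
#' threshold on a vital or lab (`sbp`, `pulse`, `k`, `egfr`, `scr`).
#'
#' @param path Path to a rules YAML file; defaults to the packaged one.
#' @return A list with elements `contraindication` and `escalation_block`,
#'   each a named list (by GDMT class) of rule records.
#' @export
read_eligibility_rules <- function(path = hfmos_extdata("eligibility_rules.yaml")) {
  rules <- yaml::read_yaml(path)
  for (kind in c("contraindication", "escalation_block")) {
    for (cls in names(rules[[kind]])) {
      if (!cls %in% GDMT_CLASSES) {
        abort(sprintf("Unknown GDMT class '%s' in %s rules.", cls, kind))
      }
      for (r in rules[[kind]][[cls]]) {
        if (!all(c("var", "op", "value") %in% names(r)) ||
            !r$op %in% c("lt", "gt")) {
          abort("Each rule needs fields var, op (lt|gt), value.")
        }
      }
    }
  }
  rules
}

#' @rdname read_eligibility_rules
#' @export
default_eligibility_rules <- function() read_eligibility_rules()
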