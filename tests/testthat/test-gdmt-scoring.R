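test_that("formulary and rules configs load and validate", {
  f <- default_formulary()
  expect_true(all(f$class %in% c("RASI", "BETA_BLOCKER", "MRA", "SGLT2I")))
  expect_true(all(f$target_daily_mg > 0))
  bad <- f
  bad$steps[[1]] <- c(40, 20) # not increasing
  expect_error(hfmos:::validate_formulary(bad), "increasing")
  r <- default_eligibility_rules()
  expect_named(r, c("contraindication", "escalation_block"))
})

test_that("classify_regimen picks the best drug per class", {
  empty <- classify_regimen(data.frame(drug = character(), daily_dose_mg = numeric()))
  expect_equal(nrow(empty), 4)
  expect_equal(empty$fraction, rep(0, 4))

  one <- classify_regimen(data.frame(drug = "carvedilol", daily_dose_mg = 50))
  expect_equal(one$fraction[one$class == "BETA_BLOCKER"], 1.0)

  # two beta-blockers at 25% and 50% of their targets: keep the second
  two <- classify_regimen(data.frame(
    drug = c("carvedilol", "metoprolol-succinate"),
    daily_dose_mg = c(12.5, 100)
  ))
  bb <- two[two$class == "BETA_BLOCKER", ]
  expect_equal(bb$fraction, 0.5)
  expect_equal(bb$drug, "metoprolol-succinate")

  expect_warning(
    classify_regimen(data.frame(drug = c("lisinopril", "sacubitril-valsartan"),
                                daily_dose_mg = c(20, 100))),
    "RASI subtypes"
  )
  expect_message(
    classify_regimen(data.frame(drug = "furosemide", daily_dose_mg = 40)),
    "non-GDMT"
  )
})

test_that("eligibility gating follows the rule table", {
  # K+ = 5.5 exceeds the MRA threshold of 5.0
  s <- patient_snapshot(sbp = 120, pulse = 75, k = 5.5, egfr = 65)
  expect_equal(assess_eligibility(s, "MRA")$status, "CONTRAINDICATED")
  # but not the RASI threshold of 5.5 (strict)
  expect_equal(assess_eligibility(s, "RASI")$status, "ELIGIBLE")

  # documented intolerance wins regardless of labs
  s2 <- patient_snapshot(sbp = 120, pulse = 75, k = 5.5, egfr = 65,
                         intolerant = "MRA")
  expect_equal(assess_eligibility(s2, "MRA")$status, "INTOLERANT")

  # SBP 90 blocks RASI escalation (rule: SBP < 95) for a partial dose,
  # without contraindicating initiation (rule: SBP < 90 strict)
  s3 <- patient_snapshot(sbp = 90, pulse = 75, k = 4.2, egfr = 65)
  expect_equal(assess_eligibility(s3, "RASI", fraction = 0.5)$status,
               "ESCALATION_BLOCKED")
  expect_equal(assess_eligibility(s3, "RASI", fraction = 0)$status, "ELIGIBLE")

  # missing labs: rules cannot fire, status conservative with annotation
  s4 <- patient_snapshot()
  e <- assess_eligibility(s4, "MRA")
  expect_equal(e$status, "ELIGIBLE")
  expect_true(e$missing_data)

  expect_equal(assess_eligibility(patient_snapshot(pulse = 50), "BETA_BLOCKER")$status,
               "CONTRAINDICATED")
})

test_that("MOS spans 0 to 100 and excludes ineligible classes from the denominator", {
  at_target <- data.frame(
    drug = c("lisinopril", "carvedilol", "spironolactone", "dapagliflozin"),
    daily_dose_mg = c(40, 50, 25, 10)
  )
  s <- compute_mos(normal_snapshot(at_target))
  expect_equal(s$mos, 100)
  expect_false(s$undefined)

  s0 <- compute_mos(normal_snapshot())
  expect_equal(s0$mos, 0)
  expect_equal(s0$assessments$recommendation, rep("INITIATE", 4))

  # RASI 0.5 + BB 1.0 + MRA intolerant + SGLT2I 0 -> 100*(0.5+1+0)/3 = 50
  s3 <- compute_mos(normal_snapshot(
    data.frame(drug = c("lisinopril", "carvedilol"), daily_dose_mg = c(20, 50)),
    intolerant = "MRA"
  ))
  expect_equal(s3$mos, 50)

  # all four classes excluded: undefined, never a silent 0 or 100
  s4 <- compute_mos(normal_snapshot(
    intolerant = c("RASI", "BETA_BLOCKER", "MRA", "SGLT2I")))
  expect_true(s4$undefined)
  expect_true(is.na(s4$mos))

  # escalation-blocked partial dose earns full credit
  low_bp <- patient_snapshot(
    data.frame(drug = c("lisinopril", "carvedilol", "spironolactone",
                        "dapagliflozin"),
               daily_dose_mg = c(20, 25, 25, 10)),
    sbp = 92, pulse = 75, k = 4.2, egfr = 65
  )
  sb <- compute_mos(low_bp)
  expect_equal(sb$assessments$status[sb$assessments$class == "RASI"],
               "ESCALATION_BLOCKED")
  expect_equal(sb$mos, 100)

  # TITRATE recommendation points at the next formulary step
  st <- compute_mos(normal_snapshot(
    data.frame(drug = "carvedilol", daily_dose_mg = 12.5)))
  bb <- st$assessments[st$assessments$class == "BETA_BLOCKER", ]
  expect_equal(bb$recommendation, "TITRATE")
  expect_equal(bb$next_dose_mg, 25)
})

test_that("HFC point scheme reproduces the printed worked cases", {
  score_hfc <- function(orders, intolerant = character()) {
    compute_mos(normal_snapshot(orders, intolerant = intolerant))$hfc
  }
  # BB at 50% target + any ARNI dose + any MRA dose = 2 + 3 + 2 = 7
  expect_equal(score_hfc(data.frame(
    drug = c("carvedilol", "sacubitril-valsartan", "spironolactone"),
    daily_dose_mg = c(25, 100, 12.5))), 7L)
  expect_equal(score_hfc(NULL), 0L)
  # ACEI at 25% of target only
  expect_equal(score_hfc(data.frame(drug = "lisinopril", daily_dose_mg = 10)), 1L)
  # ACEI at >= 50%
  expect_equal(score_hfc(data.frame(drug = "lisinopril", daily_dose_mg = 20)), 2L)
  # contraindicated class earns its slot maximum
  expect_equal(score_hfc(NULL, intolerant = c("RASI", "BETA_BLOCKER", "MRA")), 7L)
})

test_that("mHFC splits the ARNI into components and rescales by 8", {
  score_mhfc <- function(orders, intolerant = character()) {
    s <- compute_mos(normal_snapshot(orders, intolerant = intolerant))
    c(s$mhfc_points, s$mhfc_scaled)
  }
  # target-dose sacubitril/valsartan alone: 2 + 2 = 4 points, scaled 50
  expect_equal(score_mhfc(data.frame(drug = "sacubitril-valsartan",
                                     daily_dose_mg = 400)), c(4, 50))
  # BB >= 50% + target ARNI + MRA >= 50%: the maximum 8
  expect_equal(score_mhfc(data.frame(
    drug = c("carvedilol", "sacubitril-valsartan", "spironolactone"),
    daily_dose_mg = c(25, 400, 12.5))), c(8, 100))
  expect_equal(score_mhfc(NULL), c(0, 0))
  # half-target ARNI: each component below 50%... 100/400 = 25% -> 1 + 1
  expect_equal(score_mhfc(data.frame(drug = "sacubitril-valsartan",
                                     daily_dose_mg = 100))[1], 2)
})

test_that("KCMO averages dose fractions with a binary MRA", {
  kcmo <- function(orders, intolerant = character()) {
    compute_mos(normal_snapshot(orders, intolerant = intolerant))$kcmo
  }
  expect_equal(kcmo(data.frame(
    drug = c("lisinopril", "carvedilol", "spironolactone", "dapagliflozin"),
    daily_dose_mg = c(40, 50, 25, 10))), 100)
  # MRA at 10% of target, others absent: (1+0+0+0)/4
  expect_equal(kcmo(data.frame(drug = "spironolactone", daily_dose_mg = 2.5)), 25)
  # RASI at 50%, others absent: (0.5+0+0+0)/4
  expect_equal(kcmo(data.frame(drug = "lisinopril", daily_dose_mg = 20)), 12.5)
  expect_true(is.na(kcmo(NULL, intolerant = c("RASI", "BETA_BLOCKER", "MRA",
                                              "SGLT2I"))))
})

test_that("scores are monotone in dose and MOS never drops when a low class is excluded", {
  f <- default_formulary()
  set.seed(401)
  for (rep in 1:25) {
    drugs <- c("lisinopril", "carvedilol", "spironolactone", "dapagliflozin")
    fr <- runif(4)
    orders <- data.frame(drug = drugs,
                         daily_dose_mg = fr * f$target_daily_mg[match(drugs, f$drug)])
    base <- compute_mos(normal_snapshot(orders))
    # raise one drug's dose (still <= target): no score may decrease
    j <- sample(1:4, 1)
    orders2 <- orders
    target_j <- f$target_daily_mg[match(drugs[j], f$drug)]
    orders2$daily_dose_mg[j] <- min(target_j, orders2$daily_dose_mg[j] * (1 + runif(1)))
    up <- compute_mos(normal_snapshot(orders2))
    expect_gte(up$mos, base$mos - 1e-9)
    expect_gte(up$hfc, base$hfc)
    expect_gte(up$mhfc_points, base$mhfc_points)
    expect_gte(up$kcmo, base$kcmo - 1e-9)

    # marking the lowest-fraction class intolerant never decreases MOS
    low <- GDMT_CLASSES_TEST[which.min(fr)]
    excl <- compute_mos(normal_snapshot(orders, intolerant = low))
    expect_gte(excl$mos, base$mos - 1e-9)
  }
})

test_that("batch scoring equals the per-encounter engine", {
  co <- generate_cohort_tables(truth_params(6, n_intervals = 3, seed = 77))
  batch <- score_encounters(co$encounters, co$medications, co$intolerances)
  for (i in sample(seq_len(nrow(co$encounters)), 8)) {
    e <- co$encounters[i, ]
    meds <- co$medications |>
      dplyr::filter(id == e$id, date <= e$date) |>
      dplyr::group_by(drug) |>
      dplyr::slice_max(date, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::filter(daily_dose_mg > 0)
    s <- compute_mos(patient_snapshot(meds[, c("drug", "daily_dose_mg")],
                                      sbp = e$sbp, pulse = e$pulse, k = e$k,
                                      egfr = e$egfr))
    b <- batch[batch$id == e$id & batch$date == e$date, ]
    expect_equal(b$mos, s$mos, tolerance = 1e-10)
    expect_equal(b$hfc, s$hfc)
    expect_equal(b$mhfc_points, s$mhfc_points)
    expect_equal(b$kcmo, s$kcmo, tolerance = 1e-10)
  }
})
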