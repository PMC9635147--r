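test_that("medication names match by generic or brand substring, case-insensitively", {
  cat <- fixture_catalogue()
  expect_equal(match_medication("CLENIL MODULITE 100MCG INHALER", cat)$class, "ICS")
  expect_equal(match_medication("clenil modulite 100mcg inhaler", cat)$generic_name,
               "BECLOMETASONE")
  expect_equal(match_medication("  Seretide   250 Evohaler ", cat)$class, "ICS_LABA")
  expect_equal(match_medication("SALBUTAMOL 100MCG CFC FREE", cat)$class, "SABA")
  expect_null(match_medication("AMOXICILLIN 500MG CAPSULES", cat))
  expect_error(match_medication("", cat), "non-empty")
})

test_that("two matching catalogue entries raise an ambiguity error, not a silent pick", {
  cat <- fixture_catalogue()
  expect_error(match_medication("BUDESONIDE/FORMOTEROL 200/6 DRY POWDER", cat),
               "ambiguous")
})

test_that("discontinued brands resolve to rows carrying the parent drug's thresholds", {
  cat <- fixture_catalogue()
  aerobec <- match_medication("AEROBEC FORTE 250 MCG", cat)
  parent <- match_medication("BECLOMETASONE 100MCG", cat)
  expect_equal(aerobec$class, "ICS")
  expect_equal(aerobec$inhaler_type, parent$inhaler_type)
  expect_equal(
    c(aerobec$band_low, aerobec$band_medium, aerobec$band_high),
    c(parent$band_low, parent$band_medium, parent$band_high)
  )
})

test_that("exclusions fire in the documented precedence with one reason each", {
  cat <- fixture_catalogue()
  rules <- fixture_rules()
  period <- as.Date(c("2009-01-31", "2017-03-31"))
  entry <- match_medication("BECLOMETASONE NASAL SPRAY", cat)

  # a record both out of period and with an excludable formulation: period wins
  rec <- raw_record(prescribed_date = "2000-01-01",
                    medication_name = "BECLOMETASONE NASAL SPRAY",
                    formulation = "NASAL SPRAY")
  expect_equal(apply_exclusions(rec, entry, rules, period)$reason, "OUT_OF_PERIOD")

  rec$prescribed_date <- as.Date("2010-01-01")
  expect_equal(apply_exclusions(rec, entry, rules, period)$reason,
               "FORMULATION_EXCLUDED")

  rec2 <- raw_record(dose_text = "ONE SPRAY IN EACH NOSTRIL DAILY FOR RHINITIS")
  entry2 <- match_medication(rec2$medication_name, cat)
  expect_equal(apply_exclusions(rec2, entry2, rules, period)$reason,
               "NON_ASTHMA_INDICATION")

  rec3 <- raw_record(medication_name = "NASOBEC BECLOMETASONE 50MCG", formulation = "")
  entry3 <- match_medication(rec3$medication_name, cat)
  # indication/brand keywords: the name carries a nasal brand
  expect_equal(apply_exclusions(rec3, entry3, rules, period)$keep, FALSE)

  rec4 <- raw_record(dose_text = "PLEASE DELETE THIS ENTRY")
  entry4 <- match_medication(rec4$medication_name, cat)
  expect_equal(apply_exclusions(rec4, entry4, rules, period)$reason, "DELETED")

  clean <- raw_record()
  expect_true(apply_exclusions(clean, match_medication(clean$medication_name, cat),
                               rules, period)$keep)
  expect_error(apply_exclusions(raw_record(prescribed_date = NA), entry, rules, period),
               "date")
})

test_that("formulation exclusions only apply to ICS-type entries", {
  cat <- fixture_catalogue()
  rules <- fixture_rules()
  period <- as.Date(c("2009-01-31", "2017-03-31"))
  rec <- raw_record(medication_name = "VENTOLIN 100MCG", formulation = "NASAL SPRAY")
  entry <- match_medication(rec$medication_name, cat)
  expect_true(apply_exclusions(rec, entry, rules, period)$keep)
})

test_that("corticosteroid solutions are reclassified, other classes never", {
  cat <- fixture_catalogue()
  ics <- match_medication("BUDESONIDE 0.5MG RESPULES", cat)
  expect_equal(reclassify_solution(raw_record(formulation = "SOL", dose_text = ""),
                                   ics), "ORAL_OR_NEB_STEROID")
  for (txt in c("ONE RESPULE VIA NEBULISER AT NIGHT", "TWO SACHETS DAILY",
                "ONE VIAL AS DIRECTED", "ONE AMPOULE NEB")) {
    expect_equal(reclassify_solution(raw_record(formulation = "", dose_text = txt), ics),
                 "ORAL_OR_NEB_STEROID")
  }
  expect_equal(reclassify_solution(
    raw_record(formulation = "MDI", dose_text = "TWO PUFFS TWICE DAILY"), ics), "ICS")
  saba <- match_medication("VENTOLIN NEBULES", cat)
  expect_equal(reclassify_solution(raw_record(dose_text = "ONE NEB"), saba), "SABA")
})
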