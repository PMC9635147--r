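test_that("dose frequency is extracted from keyword phrases, longest first", {
  kw <- fixture_freq()
  cases <- list(
    list("TAKE TWO PUFFS TWICE DAILY", 2L),
    list("4 TIMES A DAY WHEN REQUIRED", 4L),
    list("ONE PUFF MORNING AND NIGHT", 2L),
    list("TWO PUFFS THREE TIMES A DAY", 3L),
    list("1 PUFF OD", 1L),
    list("TAKE ONE AT NIGHT NOCTE", 1L),
    list("TWO PUFFS BD", 2L),
    list("", NA_integer_),
    list("USE AS DIRECTED", NA_integer_)
  )
  for (cs in cases) {
    expect_identical(extract_frequency(cs[[1]], kw), cs[[2]], label = cs[[1]])
  }
  # longest-phrase precedence: MORNING AND NIGHT outranks the embedded MANE-free ONCE
  expect_identical(extract_frequency("ONCE EVERY MORNING AND NIGHT", kw), 2L)
})

test_that("dose quantity needs a take/inhale prefix or a daily/at/taken/puf/p suffix", {
  cases <- list(
    list("TAKE TWO PUFFS TWICE DAILY", 2L),
    list("2 PUFS AT NIGHT", 2L),          # single-'f' typo form
    list("INHALE 3 EVERY MORNING", 3L),
    list("FOUR TO BE TAKEN EACH DAY", 4L),
    list("1 DAILY", 1L),
    list("2P TWICE DAILY", 2L),
    list("TWO AT BEDTIME", 2L),
    list("USE AS DIRECTED", NA_integer_),
    list("5 PUFFS DAILY", NA_integer_),   # numbers above four are out of rule
    list("", NA_integer_)
  )
  for (cs in cases) {
    expect_identical(extract_quantity(cs[[1]]), cs[[2]], label = cs[[1]])
  }
})

test_that("strength values never parse as a proper suffix of a larger value", {
  # exhaustive over both shipped lists, with and without a space before the unit
  for (v in asthmasteps:::mcg_values) {
    expect_equal(extract_strength(paste0("DRUG ", v, "MCG"))$strength_mcg, v)
    expect_equal(extract_strength(paste0("DRUG ", v, " MCG"))$strength_mcg, v)
    expect_equal(extract_strength(paste0("DRUG ", v, " MICROGRAMS"))$strength_mcg, v)
  }
  for (v in asthmasteps:::mg_values) {
    expect_equal(extract_strength(paste0("DRUG ", v, "MG"))$strength_mcg, v * 1000)
    expect_equal(extract_strength(paste0("DRUG ", v, " MILLIGRAM"))$strength_mcg, v * 1000)
  }
  expect_equal(extract_strength("FLUTICASONE 250MCG INHALER")$strength_mcg, 250)
  expect_equal(extract_strength("BUDESONIDE 0.5MG RESPULES")$strength_mcg, 500)
  expect_true(is.na(extract_strength("USE ONE PUFF DAILY")$strength_mcg))
})

test_that("combination products split the ICS and LABA components at the slash", {
  s <- extract_strength("SERETIDE 250/25 EVOHALER", is_combo = TRUE)
  expect_equal(s$strength_mcg, 250)
  expect_equal(s$laba_component_mcg, 25)
  s2 <- extract_strength("SYMBICORT 400/12 TURBOHALER", is_combo = TRUE)
  expect_equal(s2$strength_mcg, 400)
  expect_equal(s2$laba_component_mcg, 12)
  # the unitless form ("SERETIDE 250") stays untranslated
  expect_true(is.na(extract_strength("SERETIDE 250 EVOHALER", is_combo = TRUE)$strength_mcg))
  # non-combo products do not take the slash shortcut
  expect_true(is.na(extract_strength("DRUG 250/25", is_combo = FALSE)$strength_mcg))
})

test_that("extraction is a pure function of the text", {
  txts <- c("take two puffs twice daily", "TAKE  TWO   PUFFS TWICE DAILY")
  kw <- fixture_freq()
  for (t in txts) {
    expect_identical(extract_frequency(t, kw), 2L)
    expect_identical(extract_quantity(t), 2L)
  }
  expect_equal(extract_strength("drug 250 mcg")$strength_mcg,
               extract_strength("DRUG 250MCG")$strength_mcg)
})

test_that("mode imputation fills absences, ties to the smaller value, conserves data", {
  tab <- tibble::tibble(
    med_key = c(rep("A", 4), rep("B", 4)),
    frequency_per_day = c(2, 2, 1, NA, 1, 1, 2, 2),
    quantity_per_dose = c(1, 1, 1, 1, NA, NA, 2, 2),
    strength_mcg = c(100, 100, 200, NA, 400, 400, 400, NA)
  )
  out <- impute_by_mode(tab)
  expect_equal(out$frequency_per_day[4], 2)          # plain mode
  # B's frequencies {1,1,2,2}: no absence, untouched; quantity tie {2,2} fills 2
  expect_equal(out$quantity_per_dose[5:6], c(2, 2))
  expect_equal(out$strength_mcg[4], 100)
  expect_equal(out$strength_mcg[8], 400)
  expect_identical(out$imputed_frequency, c(rep(FALSE, 3), TRUE, rep(FALSE, 4)))
  # observed values never altered
  expect_equal(out$frequency_per_day[-4], tab$frequency_per_day[-4])
  # tie-break to the smallest value
  tie <- tibble::tibble(med_key = "C", frequency_per_day = c(1, 1, 2, 2, NA),
                        quantity_per_dose = 1, strength_mcg = 100)
  expect_equal(impute_by_mode(tie)$frequency_per_day[5], 1)
})

test_that("imputation leaves fields absent when nothing was observed, and handles edges", {
  none <- tibble::tibble(med_key = "A", frequency_per_day = NA_real_,
                         quantity_per_dose = NA_real_, strength_mcg = NA_real_)
  out <- impute_by_mode(none)
  expect_true(is.na(out$frequency_per_day))
  expect_false(out$imputed_frequency)
  empty <- impute_by_mode(none[0, ])
  expect_equal(nrow(empty), 0)
  full <- tibble::tibble(med_key = "A", frequency_per_day = c(1, 2),
                         quantity_per_dose = c(1, 1), strength_mcg = c(100, 100))
  expect_equal(impute_by_mode(full)$frequency_per_day, c(1, 2))
})

test_that("strengths outside the licensed range are flagged", {
  cat <- fixture_catalogue()
  flu <- match_medication("FLUTICASONE INHALER", cat)
  expect_true(validate_strength(flu, 250))
  expect_false(validate_strength(flu, 10000))
  expect_false(validate_strength(flu, 60))
})

test_that("daily dose is the product of the three components and propagates absence", {
  expect_equal(daily_dose(2, 2, 100), 400)
  expect_equal(daily_dose(1, 1, 500), 500)
  expect_true(is.na(daily_dose(NA, 2, 100)))
  # monotone non-decreasing in each component
  base <- daily_dose(2, 2, 100)
  expect_true(daily_dose(3, 2, 100) >= base)
  expect_true(daily_dose(2, 3, 100) >= base)
  expect_true(daily_dose(2, 2, 200) >= base)
})
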