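# helper: a retained-prescription row for regimen building
rx <- function(day, med_key, class, band = NA_character_, patient_id = "P1") {
  tibble::tibble(patient_id = patient_id,
                 prescribed_date = as.Date("2010-01-01") + day,
                 med_key = med_key, class = class, band = band)
}

test_that("same-day prescriptions condense to one candidate event per date", {
  recs <- dplyr::bind_rows(
    rx(0, "BECLOMETASONE", "ICS", "LOW"),
    rx(0, "SALBUTAMOL", "SABA"),
    rx(10, "SALBUTAMOL", "SABA")
  )
  ev <- condense_same_day(recs)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$event_date, as.Date("2010-01-01") + c(0, 10))
  expect_equal(nrow(condense_same_day(recs[1, ])), 1)
  # duplicate rows collapse too
  expect_equal(nrow(condense_same_day(dplyr::bind_rows(recs[1, ], recs[1, ]))), 1)
})

test_that("the lookback window is inclusive of the index date and 120 days long", {
  hist <- dplyr::bind_rows(
    rx(0, "BECLOMETASONE", "ICS", "LOW"),
    rx(60, "SALMETEROL", "LABA")
  )
  reg <- build_regimen(hist, as.Date("2010-01-01") + 100)
  expect_equal(reg$ics_band, "LOW")
  expect_equal(reg$addons, "LABA")
  expect_equal(reg$label, "Low-strength ICS + LABA")

  # 120 days before the index is outside the window
  hist2 <- dplyr::bind_rows(rx(0, "BECLOMETASONE", "ICS", "LOW"),
                            rx(121, "SALBUTAMOL", "SABA"))
  reg2 <- build_regimen(hist2, as.Date("2010-01-01") + 121)
  expect_true(reg2$saba_only)
  expect_equal(reg2$ics_band, "NONE")
  expect_equal(reg2$label, "SABA")
  # at 119 days apart the ICS is still in the window
  reg3 <- build_regimen(hist2, as.Date("2010-01-01") + 119)
  expect_equal(reg3$ics_band, "LOW")
  # empty window yields no regimen
  expect_null(build_regimen(hist[0, ], as.Date("2010-01-01")))
})

test_that("the window band takes each product's most recent dose, max across products", {
  hist <- dplyr::bind_rows(
    rx(0, "BECLOMETASONE", "ICS", "HIGH"),
    rx(30, "BECLOMETASONE", "ICS", "MEDIUM"),   # most recent beclometasone
    rx(10, "SERETIDE", "ICS_LABA", "LOW")
  )
  reg <- build_regimen(hist, as.Date("2010-01-01") + 40)
  expect_equal(reg$ics_band, "MEDIUM")          # not the older HIGH
  expect_true("LABA" %in% reg$addons)           # combination inhaler adds LABA
  # UNKNOWN dominates when present
  hist2 <- dplyr::bind_rows(rx(0, "BECLOMETASONE", "ICS", "UNKNOWN"),
                            rx(5, "SERETIDE", "ICS_LABA", "HIGH"))
  expect_equal(build_regimen(hist2, as.Date("2010-01-05"))$ics_band, "UNKNOWN")
})

test_that("SABA is a reliever: never an add-on, and saba_only only when alone", {
  hist <- dplyr::bind_rows(rx(0, "BECLOMETASONE", "ICS", "LOW"),
                           rx(0, "SALBUTAMOL", "SABA"))
  reg <- build_regimen(hist, as.Date("2010-01-01"))
  expect_equal(reg$addons, character(0))
  expect_false(reg$saba_only)
  expect_equal(reg$label, "Low-strength ICS")
  expect_error(new_regimen("LOW", saba_only = TRUE), "saba_only")
})

test_that("regimens are invariant to input row order and to out-of-window rows", {
  hist <- dplyr::bind_rows(
    rx(0, "BECLOMETASONE", "ICS", "LOW"),
    rx(20, "SALMETEROL", "LABA"),
    rx(40, "MONTELUKAST", "LTRA"),
    rx(-500, "SERETIDE", "ICS_LABA", "HIGH")    # far outside every window
  )
  idx <- as.Date("2010-01-01") + 50
  base <- build_regimen(hist, idx)
  set.seed(9)
  for (i in 1:10) {
    perm <- hist[sample(nrow(hist)), ]
    expect_identical(build_regimen(perm, idx), base)
  }
  expect_identical(build_regimen(hist[-4, ], idx), base)
})

test_that("run-in events are dropped up to study_start + window", {
  ev <- tibble::tibble(patient_id = "P1",
                       event_date = as.Date("2009-01-31") + c(0, 119, 120, 200))
  out <- apply_run_in(ev, as.Date("2009-01-31"))
  expect_equal(out$event_date, as.Date("2009-01-31") + c(120, 200))
  expect_equal(nrow(apply_run_in(ev[0, ], as.Date("2009-01-31"))), 0)
})

test_that("the event table carries regimen labels and steps per event", {
  recs <- dplyr::bind_rows(
    rx(0, "BECLOMETASONE", "ICS", "LOW"),
    rx(30, "BECLOMETASONE", "ICS", "LOW"),
    rx(60, "SERETIDE", "ICS_LABA", "MEDIUM"),
    rx(0, "SALBUTAMOL", "SABA", patient_id = "P2")
  )
  ev <- build_event_table(recs, fixture_steps())
  expect_equal(nrow(ev), 4)
  p1 <- ev[ev$patient_id == "P1", ]
  expect_equal(p1$step, c(1L, 1L, 3L))   # medium combo takes over at day 60
  expect_equal(p1$regimen[3], "Medium-strength ICS + LABA")
  expect_equal(ev$step[ev$patient_id == "P2"], 0L)
})
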