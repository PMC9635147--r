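test_that("episode durations run to the start of the next episode; the last is censored", {
  ep <- build_episodes(events_for(c(0, 100, 200), c(1, 1, 2)))
  expect_equal(nrow(ep), 2)
  expect_equal(ep$duration_days[1], 200L)     # not 100: ends at the step-2 event
  expect_equal(ep$direction, c("UP", "CENSORED"))
  expect_equal(ep$next_step, c(2L, NA_integer_))

  ep2 <- build_episodes(events_for(c(0, 50, 300), c(3, 4, 3)))
  expect_equal(ep2$duration_days, c(50L, 250L, 0L))
  expect_equal(ep2$direction, c("UP", "DOWN", "CENSORED"))

  one <- build_episodes(events_for(0, 2))
  expect_equal(one$direction, "CENSORED")
  expect_equal(one$duration_days, 0L)
  expect_equal(nrow(build_episodes(events_for(numeric(0), integer(0)))), 0)
})

test_that("episodes agree with a brute-force oracle over all short step sequences", {
  grids <- expand.grid(rep(list(0:2), 5))          # 3^5 step sequences
  days <- c(0, 37, 90, 181, 260)
  for (i in seq_len(nrow(grids))) {
    steps <- as.integer(unlist(grids[i, ]))
    got <- build_episodes(events_for(days, steps))
    ref <- reference_episodes(days, steps)
    expect_equal(got$step, ref$step)
    expect_equal(got$duration_days, as.integer(ref$duration))
    expect_equal(got$direction, ref$direction)
    expect_equal(got$next_step, as.integer(ref$next_step))
  }
})

test_that("episode construction ignores event order and duplicate dates", {
  ev <- events_for(c(0, 30, 60, 90), c(1, 1, 2, 1))
  base <- build_episodes(ev)
  shuffled <- ev[c(3, 1, 4, 2), ]
  expect_identical(build_episodes(shuffled), base)
  dup <- dplyr::bind_rows(ev, ev[2, ])
  expect_identical(build_episodes(dup), base)
})

test_that("within-step regimen changes are counted between consecutive same-step events", {
  ev <- events_for(c(0, 30, 60, 90), c(2, 2, 2, 3))
  ev$regimen <- c("Low-strength ICS + LABA", "Low-strength ICS + LTRA",
                  "Low-strength ICS + LTRA", "Medium-strength ICS")
  ep <- build_episodes(ev)
  expect_equal(ep$regimen_changes_within, c(1L, 0L))
})

test_that("duration summaries use uncensored episodes and disclose censoring", {
  eps <- dplyr::bind_rows(
    build_episodes(events_for(c(0, 100, 200), c(1, 2, 1))),
    build_episodes(events_for(c(0, 300), c(3, 2), patient_id = "P2"))
  )
  s <- summarise_durations(eps)
  expect_equal(s$overall$n, 3L)                       # 5 episodes, 2 censored
  expect_equal(s$overall$pct_censored, 100 * 2 / 5)
  expect_equal(s$overall$median_days, 100)
  up <- s$by_direction[s$by_direction$direction == "UP", ]
  down <- s$by_direction[s$by_direction$direction == "DOWN", ]
  expect_equal(up$n, 1L)
  expect_equal(up$median_days, 100)
  expect_equal(down$n, 2L)
  expect_equal(down$median_days, 200)
  # a stratum with only censored episodes reports NA, not zero
  s2 <- summarise_durations(build_episodes(events_for(0, 4)))
  expect_equal(s2$overall$n, 0L)
  expect_true(is.na(s2$overall$median_days))
  expect_equal(s2$by_step$pct_censored[s2$by_step$step == 4], 100)
})

test_that("the transition matrix counts changes off-diagonal, regimen switches on it", {
  ev <- events_for(c(0, 30, 60, 90, 120), c(1, 2, 2, 3, 2))
  ev$regimen <- c("a", "b", "c", "d", "e")        # every same-step pair differs
  eps <- build_episodes(ev)
  tm <- transition_matrix(eps)
  m <- tm$matrix
  expect_equal(m["1", "2"], 1)
  expect_equal(m["2", "3"], 1)
  expect_equal(m["3", "2"], 1)
  expect_equal(m["2", "2"], 1)                     # b -> c within step 2
  expect_equal(sum(m), 4)
  expect_equal(tm$single_step_fraction_up, 100)
  expect_equal(tm$single_step_fraction_down, 100)
  expect_true(all(tm$long$from != tm$long$to))
  expect_equal(sum(tm$long$n), 3)

  # a two-step jump halves the single-step fraction
  eps2 <- build_episodes(events_for(c(0, 10, 20), c(1, 3, 4)))
  expect_equal(transition_matrix(eps2)$single_step_fraction_up, 50)
})

test_that("step-0 exclusion drops transitions touching step 0", {
  eps <- build_episodes(events_for(c(0, 30, 60, 90), c(1, 0, 1, 2)))
  full <- transition_matrix(eps)
  noz <- transition_matrix(eps, exclude_step0 = TRUE)
  expect_equal(sum(full$matrix), 3)
  expect_equal(sum(noz$matrix), 1)                 # only 1 -> 2 survives
  expect_equal(dim(noz$matrix), c(4, 4))
  expect_false("0" %in% rownames(noz$matrix))
})

test_that("person-years anchor at the first event and count distinct steps and changes", {
  ev <- events_for(c(0, 100, 200, 400, 500), c(2, 3, 2, 2, 2))
  py <- person_year_summary(ev)
  expect_equal(nrow(py$per_year), 2)
  y1 <- py$per_year[py$per_year$year_index == 1, ]
  expect_equal(y1$n_events, 3L)
  expect_equal(y1$distinct_steps, 2L)              # steps {2, 3}
  expect_equal(y1$n_changes, 2L)                   # 2->3 and 3->2
  y2 <- py$per_year[py$per_year$year_index == 2, ]
  expect_equal(c(y2$distinct_steps, y2$n_changes), c(1L, 0L))
  expect_equal(py$aggregate$person_years, 2L)
  expect_equal(py$aggregate$pct_single_step, 50)

  # a year-long silent gap leaves no person-year block for it
  ev2 <- events_for(c(0, 800), c(1, 1), patient_id = "P2")
  py2 <- person_year_summary(ev2)
  expect_equal(sort(py2$per_year$year_index), c(1L, 3L))
})
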