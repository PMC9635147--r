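# shared fixtures and reference implementations, built in code

fixture_catalogue <- function() read_catalogue()
fixture_rules <- function() read_exclusion_rules()
fixture_freq <- function() read_frequency_keywords()
fixture_steps <- function() read_step_rules()

# a minimal raw prescription row
raw_record <- function(patient_id = "ID001", prescribed_date = "2009-07-01",
                       medication_name = "CLENIL MODULITE 100MCG INHALER",
                       formulation = "MDI",
                       dose_text = "TAKE TWO PUFFS TWICE DAILY", ...) {
  tibble::tibble(patient_id = patient_id,
                 prescribed_date = as.Date(prescribed_date),
                 medication_name = medication_name,
                 formulation = formulation,
                 dose_text = dose_text, ...)
}

# naive reference for episode construction: walks the run-length encoding of
# the step sequence directly
reference_episodes <- function(days, steps) {
  r <- rle(steps)
  starts_idx <- cumsum(c(1, head(r$lengths, -1)))
  n <- length(r$values)
  data.frame(
    step = r$values,
    start = days[starts_idx],
    end = c(days[starts_idx[-1]], days[length(days)]),
    next_step = c(r$values[-1], NA),
    duration = c(days[starts_idx[-1]], days[length(days)]) - days[starts_idx],
    direction = ifelse(is.na(c(r$values[-1], NA)), "CENSORED",
                       ifelse(c(r$values[-1], NA) > r$values, "UP", "DOWN"))
  )
}

events_for <- function(days, steps, patient_id = "P1") {
  tibble::tibble(patient_id = patient_id,
                 event_date = as.Date("2010-01-01") + days,
                 step = steps)
}

# small cohort used across tests; memoised per session for speed
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_patients = 25, study_end = "2011-07-31",
                               text_noise = noise_off(), seed = 42)
      cache <<- list(cfg = cfg, sim = simulate_cohort(cfg))
    }
    cache
  }
})
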