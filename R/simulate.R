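#' Synthetic prescription cohort with known ground truth
#'
#' Real prescribing datasets of this kind are access-controlled, so the
#' package ships a generator that emulates their structure: staggered ~30-day
#' refills, free-text dose directions in varied phrasings (including the
#' "PUFS" typo and Latin abbreviations), brand versus generic medication
#' names, strengths embedded in the medication name, and latent per-patient
#' step trajectories. Every emitted record carries its true frequency,
#' quantity, strength, class and dose band, so each pipeline stage can be
#' checked against ground truth.
#'
#' The latent process changes step only at refill ("review") times, since
#' steps are only observable at prescription events. On entering a step the
#' next change direction is drawn first, then the dwell time from a geometric
#' distribution over review cycles whose mean depends on the direction; the
#' default step-down dwell (300 days) is longer than the step-up dwell
#' (130 days), mirroring the clinical asymmetry between stepping up and
#' stepping down treatment.
#'
#' @name synthetic_cohort
NULL

#' Simulation configuration
#'
#' @param n_patients number of patients.
#' @param study_start,study_end study period (coerced to Date). The default
#'   five-year window gives each patient a multi-episode trajectory.
#' @param dwell_means_days named numeric, mean dwell in days before a step
#'   `up` and before a step `down`.
#' @param p_up_by_step probability that the next change from steps 0-4 is a
#'   step up (forced 1 at step 0 and 0 at step 4).
#' @param initial_step_probs distribution of the step at cohort entry.
#' @param refill_interval_days mean days between refills of a component.
#' @param refill_jitter_days refills are jittered uniformly by up to this
#'   many days either way.
#' @param p_within_step_change per-review probability of switching to a
#'   different product realisation of the same step.
#' @param p_saba_coprescription probability that a reliever (SABA) is
#'   co-prescribed alongside a controller regimen.
#' @param text_noise list of probabilities: `typo_puf` (render "PUFS"),
#'   `missing_strength` (omit the strength token), `missing_frequency`,
#'   `missing_quantity` (omit that component from the directions),
#'   `unit_space` ("250 MCG" rather than "250MCG"), `brand` (render the
#'   brand name rather than the generic). Defaults approximate the
#'   missingness rates seen in real free-text dose directions (~10%
#'   frequency/quantity, ~8% strength).
#' @param seed integer; fully determines the output.
#' @return a config list for [simulate_cohort()].
#' @export
simulation_config <- function(n_patients = 500,
                              study_start = "2009-01-31",
                              study_end = "2014-01-31",
                              dwell_means_days = c(up = 130, down = 300),
                              p_up_by_step = c(1, 0.7, 0.6, 0.5, 0),
                              initial_step_probs = c(0.25, 0.2, 0.1, 0.2, 0.25),
                              refill_interval_days = 30,
                              refill_jitter_days = 3,
                              p_within_step_change = 0.1,
                              p_saba_coprescription = 0.4,
                              text_noise = list(typo_puf = 0.05,
                                                missing_strength = 0.08,
                                                missing_frequency = 0.10,
                                                missing_quantity = 0.10,
                                                unit_space = 0.3,
                                                brand = 0.7),
                              seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              study_start = as.Date(study_start),
              study_end = as.Date(study_end),
              dwell_means_days = dwell_means_days,
              p_up_by_step = p_up_by_step,
              initial_step_probs = initial_step_probs,
              refill_interval_days = refill_interval_days,
              refill_jitter_days = refill_jitter_days,
              p_within_step_change = p_within_step_change,
              p_saba_coprescription = p_saba_coprescription,
              text_noise = text_noise,
              seed = as.integer(seed))
  stopifnot(cfg$study_start < cfg$study_end,
            all(unlist(cfg$text_noise) >= 0), all(unlist(cfg$text_noise) <= 1),
            all(cfg$p_up_by_step >= 0), all(cfg$p_up_by_step <= 1),
            cfg$refill_interval_days > 0)
  cfg
}

#' Zero text-noise settings (round-trip testing)
#' @return a `text_noise` list with all degradation probabilities at zero.
#' @export
noise_off <- function() {
  list(typo_puf = 0, missing_strength = 0, missing_frequency = 0,
       missing_quantity = 0, unit_space = 0, brand = 0.7)
}

# --- component and realisation tables -------------------------------------
# Each component is a concrete product at a concrete strength/frequency/
# quantity; `band` is the daily-dose band the component's prescribed daily
# dose falls in on its own thresholds (stated here directly, as ground truth,
# not derived through the banding code under test).
sim_component <- function(key, generic, brand, class, strength, laba, freq, qty,
                          band, form, unit = "MCG") {
  list(key = key, generic = generic, brand = brand, class = class,
       strength = strength, laba = laba, freq = freq, qty = qty,
       band = band, form = form, unit = unit)
}

sim_components <- list(
  saba = sim_component("SALBUTAMOL", "SALBUTAMOL", "VENTOLIN", "SABA",
                       100, NA, 4L, 2L, NA, "MDI"),
  salmeterol = sim_component("SALMETEROL", "SALMETEROL", "SEREVENT", "LABA",
                             50, NA, 2L, 2L, NA, "MDI"),
  montelukast = sim_component("MONTELUKAST", "MONTELUKAST", "SINGULAIR", "LTRA",
                              10000, NA, 1L, 1L, NA, "TAB", unit = "MG"),
  theophylline = sim_component("THEOPHYLLINE", "THEOPHYLLINE", "UNIPHYLLIN",
                               "THEOPHYLLINE", NA, NA, 2L, 1L, NA, "TAB"),
  clenil_low = sim_component("BECLOMETASONE", "BECLOMETASONE", "CLENIL", "ICS",
                             100, NA, 2L, 2L, "LOW", "MDI"),
  pulmicort_low = sim_component("BUDESONIDE", "BUDESONIDE", "PULMICORT", "ICS",
                                100, NA, 2L, 2L, "LOW", "DPI"),
  flixotide_low = sim_component("FLUTICASONE", "FLUTICASONE", "FLIXOTIDE", "ICS",
                                50, NA, 2L, 2L, "LOW", "MDI"),
  clenil_med = sim_component("BECLOMETASONE", "BECLOMETASONE", "CLENIL", "ICS",
                             200, NA, 2L, 2L, "MEDIUM", "MDI"),
  pulmicort_med = sim_component("BUDESONIDE", "BUDESONIDE", "PULMICORT", "ICS",
                                200, NA, 2L, 2L, "MEDIUM", "DPI"),
  clenil_high = sim_component("BECLOMETASONE", "BECLOMETASONE", "CLENIL", "ICS",
                              250, NA, 2L, 2L, "HIGH", "MDI"),
  seretide_low = sim_component("SERETIDE", "SERETIDE", "SERETIDE", "ICS_LABA",
                               50, 25, 2L, 2L, "LOW", "MDI"),
  seretide_med = sim_component("SERETIDE", "SERETIDE", "SERETIDE", "ICS_LABA",
                               125, 25, 2L, 2L, "MEDIUM", "MDI"),
  seretide_high = sim_component("SERETIDE", "SERETIDE", "SERETIDE", "ICS_LABA",
                                250, 25, 2L, 2L, "HIGH", "MDI"),
  symbicort_med = sim_component("SYMBICORT", "SYMBICORT", "SYMBICORT", "ICS_LABA",
                                200, 6, 2L, 2L, "MEDIUM", "DPI"),
  symbicort_high = sim_component("SYMBICORT", "SYMBICORT", "SYMBICORT", "ICS_LABA",
                                 400, 6, 2L, 2L, "HIGH", "DPI"),
  fostair_low = sim_component("FOSTAIR", "FOSTAIR", "FOSTAIR", "ICS_LABA",
                              100, 6, 1L, 1L, "LOW", "MDI")
)

# realisations per step; `safe` realisations may be switched between within a
# step interval (any union of two safe realisations of a step still
# classifies to that step, which keeps event-level truth at the step during
# the lookback carryover of a within-step switch)
sim_realisations <- list(
  `0` = list(list(comps = "saba", safe = TRUE),
             list(comps = "salmeterol", safe = TRUE),
             list(comps = "montelukast", safe = TRUE)),
  `1` = list(list(comps = "clenil_low", safe = TRUE),
             list(comps = "pulmicort_low", safe = TRUE),
             list(comps = "flixotide_low", safe = TRUE)),
  `2` = list(list(comps = "seretide_low", safe = TRUE),
             list(comps = "fostair_low", safe = TRUE),
             list(comps = c("clenil_low", "salmeterol"), safe = TRUE)),
  `3` = list(list(comps = "seretide_med", safe = TRUE),
             list(comps = "symbicort_med", safe = TRUE),
             list(comps = c("clenil_med", "salmeterol"), safe = TRUE),
             list(comps = "pulmicort_med", safe = TRUE),
             list(comps = c("seretide_low", "montelukast"), safe = FALSE)),
  `4` = list(list(comps = "seretide_high", safe = TRUE),
             list(comps = "symbicort_high", safe = TRUE),
             list(comps = c("clenil_high", "salmeterol"), safe = TRUE),
             list(comps = c("seretide_high", "montelukast"), safe = TRUE),
             list(comps = c("symbicort_high", "theophylline"), safe = TRUE),
             list(comps = c("seretide_med", "montelukast"), safe = TRUE))
)

freq_phrases <- list(
  `1` = c("ONCE DAILY", "OD", "NOCTE"),
  `2` = c("TWICE DAILY", "MORNING AND NIGHT", "BD"),
  `3` = c("THREE TIMES DAILY", "TDS"),
  `4` = c("FOUR TIMES A DAY", "QDS", "4 TIMES A DAY WHEN REQUIRED")
)

qty_words <- c("ONE", "TWO", "THREE", "FOUR")

#' Render a free-text dose direction
#'
#' Produces phrasings that the extraction rules parse back to the given
#' frequency, quantity and strength when no degradation flag is set; noise
#' flags reproduce the defects seen in real records (the "PUFS" typo, which
#' the single-'f' rule still parses; dropped frequency/quantity/strength).
#'
#' @param frequency doses per day (1-4).
#' @param quantity puffs per dose (1-4).
#' @param strength_mcg strength token to embed, `NA` to omit (strength
#'   usually lives in the medication name instead).
#' @param template_id integer selecting the phrasing template (recycled
#'   modulo the number of templates).
#' @param noise list of logical flags `typo`, `drop_strength`,
#'   `drop_frequency`, `drop_quantity`.
#' @return a single dose-direction string.
#' @export
#' @examples
#' render_dose_text(2, 2, template_id = 1)
render_dose_text <- function(frequency, quantity, strength_mcg = NA,
                             template_id = 1L,
                             noise = list()) {
  flags <- utils::modifyList(list(typo = FALSE, drop_strength = FALSE,
                                  drop_frequency = FALSE, drop_quantity = FALSE),
                             noise)
  tid <- ((as.integer(template_id) - 1L) %% 6L) + 1L
  fp <- freq_phrases[[as.character(frequency)]]
  fphrase <- fp[((tid - 1L) %% length(fp)) + 1L]
  if (flags$drop_frequency) fphrase <- "AS DIRECTED"
  puffs <- if (flags$typo) "PUFS" else "PUFFS"
  q <- as.integer(quantity)
  qw <- qty_words[q]
  body <- if (flags$drop_quantity) {
    paste("USE INHALER", fphrase)
  } else {
    switch(tid,
           paste("TAKE", qw, puffs, fphrase),
           paste("INHALE", q, fphrase),
           paste(q, puffs, fphrase),
           paste(qw, "TO BE TAKEN", fphrase),
           paste0(q, "P ", fphrase),
           paste("TAKE", q, puffs, fphrase))
  }
  if (!is.na(strength_mcg) && !flags$drop_strength) {
    body <- paste0(body, " ", format(strength_mcg, scientific = FALSE), "MCG")
  }
  body
}

# medication name rendering: brand or generic, usually carrying the strength
# token ("CLENIL 100MCG INHALER", "SERETIDE 250/25 EVOHALER")
render_med_name <- function(comp, use_brand, unit_space, drop_strength) {
  base <- if (use_brand) comp$brand else comp$generic
  token <- ""
  if (!drop_strength && !is.na(comp$strength)) {
    if (comp$class == "ICS_LABA") {
      token <- paste0(" ", comp$strength, "/", comp$laba)
    } else if (identical(comp$unit, "MG")) {
      token <- paste0(" ", format(comp$strength / 1000, scientific = FALSE), "MG")
    } else {
      token <- paste0(" ", comp$strength, if (unit_space) " MCG" else "MCG")
    }
  }
  suffix <- switch(comp$form, MDI = " INHALER", DPI = " TURBOHALER", " TABLETS")
  paste0(base, token, suffix)
}

sample_one <- function(x) if (length(x) == 1) x else sample(x, 1)

#' Simulate a prescription cohort with ground truth
#'
#' @param config list from [simulation_config()].
#' @return list with `prescriptions` (the raw prescription-record table:
#'   `patient_id`, `prescribed_date`, `dispensed_date`, `medication_name`,
#'   `bnf_code`, `formulation`, `prescribed_quantity`, `dispensed_quantity`,
#'   `dose_text`), and `truth`: `records` (one row per prescription with the
#'   true frequency/quantity/strength/class/band), `intervals` (the latent
#'   step intervals), and `events` (per prescription day, the step the
#'   pipeline should assign under the 120-day lookback, computed from the
#'   true component classes and bands), plus the `config` used.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n_days <- as.integer(config$study_end - config$study_start)
  refill <- config$refill_interval_days
  jit <- config$refill_jitter_days
  noise <- config$text_noise
  p_change_dir <- refill / config$dwell_means_days  # per-review change prob

  cols <- list()
  tcols <- list()
  icols <- list()
  k <- 0L
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("ID%05d", p)
    entry <- sample(0:45, 1)
    step <- sample(0:4, 1, prob = config$initial_step_probs)
    t <- entry
    interval_id <- 0L
    while (t < n_days) {
      interval_id <- interval_id + 1L
      up <- if (step == 0) {
        TRUE
      } else if (step == 4) {
        FALSE
      } else {
        runif(1) < config$p_up_by_step[step + 1]
      }
      dirn <- if (up) "up" else "down"
      cycles <- 1L + rgeom(1, p_change_dir[[dirn]])
      t_end <- min(t + cycles * refill, n_days)

      reals <- sim_realisations[[as.character(step)]]
      ridx <- sample_one(seq_along(reals))
      saba_co <- step > 0 && runif(1) < config$p_saba_coprescription
      safe_set <- which(vapply(reals, `[[`, logical(1), "safe"))

      day <- t
      while (day < t_end) {
        comps <- reals[[ridx]]$comps
        if (saba_co && step > 0) comps <- c(comps, "saba")
        for (cname in comps) {
          comp <- sim_components[[cname]]
          drop_s <- runif(1) < noise$missing_strength
          drop_f <- runif(1) < noise$missing_frequency
          drop_q <- runif(1) < noise$missing_quantity
          typo <- runif(1) < noise$typo_puf
          use_brand <- runif(1) < noise$brand
          unit_space <- runif(1) < noise$unit_space
          tid <- sample_one(1:6)
          # reliever directions always carry the as-needed phrasing
          if (comp$class == "SABA") tid <- 6L
          dtext <- render_dose_text(comp$freq, comp$qty, NA, tid,
                                    list(typo = typo, drop_frequency = drop_f,
                                         drop_quantity = drop_q))
          name <- render_med_name(comp, use_brand, unit_space, drop_s)
          k <- k + 1L
          cols[[k]] <- list(patient_id = pid, day = day,
                            disp = day + sample(0:3, 1),
                            name = name, form = comp$form, dose_text = dtext)
          tcols[[k]] <- list(patient_id = pid, day = day, med_key = comp$key,
                             class = comp$class, band = comp$band %||% NA_character_,
                             freq = comp$freq, qty = comp$qty,
                             strength = comp$strength,
                             strength_rendered = !drop_s && !is.na(comp$strength),
                             interval_id = interval_id)
        }
        # possible within-step product switch at the next review
        if (length(safe_set) > 1 && ridx %in% safe_set &&
            runif(1) < config$p_within_step_change) {
          ridx <- sample_one(setdiff(safe_set, ridx))
        }
        day <- day + refill + sample(-jit:jit, 1)
      }
      icols[[length(icols) + 1L]] <-
        list(patient_id = pid, interval_id = interval_id, step = step,
             start_day = t, end_day = t_end)
      step <- step + if (up) 1L else -1L
      t <- t_end
    }
  }

  grab <- function(lst, f) unlist(lapply(lst, `[[`, f), use.names = FALSE)
  prescriptions <- tibble::tibble(
    patient_id = grab(cols, "patient_id"),
    prescribed_date = config$study_start + grab(cols, "day"),
    dispensed_date = config$study_start + grab(cols, "disp"),
    medication_name = grab(cols, "name"),
    bnf_code = "0302000",
    formulation = grab(cols, "form"),
    prescribed_quantity = 1,
    dispensed_quantity = 1,
    dose_text = grab(cols, "dose_text")
  )
  truth_records <- tibble::tibble(
    patient_id = grab(tcols, "patient_id"),
    prescribed_date = config$study_start + grab(tcols, "day"),
    med_key = grab(tcols, "med_key"),
    class = grab(tcols, "class"),
    band = grab(tcols, "band"),
    frequency_per_day = grab(tcols, "freq"),
    quantity_per_dose = grab(tcols, "qty"),
    strength_mcg = grab(tcols, "strength"),
    strength_rendered = grab(tcols, "strength_rendered"),
    interval_id = grab(tcols, "interval_id")
  )
  intervals <- tibble::tibble(
    patient_id = grab(icols, "patient_id"),
    interval_id = grab(icols, "interval_id"),
    step = grab(icols, "step"),
    start_date = config$study_start + grab(icols, "start_day"),
    end_date = config$study_start + grab(icols, "end_day")
  )
  events <- truth_event_steps(truth_records, window_days = 120)
  list(prescriptions = prescriptions,
       truth = list(records = truth_records, intervals = intervals,
                    events = events),
       config = config)
}

# event-level expected steps under the lookback convention, computed from the
# true component classes and bands (never through text parsing, dose
# arithmetic or the banding rules)
truth_event_steps <- function(truth_records, window_days = 120,
                              step_rules = read_step_rules()) {
  out <- lapply(split(truth_records, truth_records$patient_id), function(tr) {
    dates <- sort(unique(as.numeric(tr$prescribed_date)))
    d <- as.numeric(tr$prescribed_date)
    step <- vapply(dates, function(ed) {
      win <- tr[d > ed - window_days & d <= ed, ]
      sel <- win$class %in% c("ICS", "ICS_LABA")
      band <- "NONE"
      if (any(sel)) {
        key <- win$med_key[sel]
        wd <- as.numeric(win$prescribed_date[sel])
        bnum <- match(win$band[sel], band_levels)
        best <- 1L
        for (kk in unique(key)) {
          i <- key == kk
          best <- max(best, max(bnum[i & wd == max(wd[i])]))
        }
        band <- band_levels[best]
      }
      addons <- unique(intersect(win$class, addon_classes))
      if ("ICS_LABA" %in% win$class) addons <- unique(c(addons, "LABA"))
      classify_step_core(band, length(addons), step_rules)
    }, integer(1))
    tibble::tibble(patient_id = tr$patient_id[1],
                   event_date = as.Date(dates, origin = "1970-01-01"),
                   true_step = step)
  })
  dplyr::bind_rows(out)
}
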