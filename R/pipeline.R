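#' End-to-end prescription processing pipeline
#'
#' Runs the stages in order: identify medications, apply exclusions, extract
#' dose components from free text, impute by mode, validate strengths, band
#' daily doses, condense same-day prescriptions, evaluate the lookback
#' regimen at each prescription event, classify treatment steps, drop run-in
#' events, and summarise trajectories. Every input row receives exactly one
#' disposition; unusable rows are quarantined to a reject table, never
#' silently dropped, and the attrition report accounts for every row:
#' `total_input = retained + sum(excluded) + quarantined`.
#'
#' @name pipeline
NULL

exclusion_reason_levels <- c("OUT_OF_PERIOD", "DELETED", "NO_MATCH",
                             "FORMULATION_EXCLUDED", "NON_ASTHMA_INDICATION",
                             "NON_ASTHMA_BRAND", "STRENGTH_OUT_OF_RANGE")

#' Run the full pipeline on a prescription-record table
#'
#' @param input tibble/data.frame of raw prescription records with columns
#'   `patient_id`, `prescribed_date`, `medication_name`, `dose_text`, and
#'   optionally `dispensed_date`, `bnf_code`, `formulation`,
#'   `prescribed_quantity`, `dispensed_quantity`.
#' @param catalogue from [read_catalogue()].
#' @param exclusions from [read_exclusion_rules()].
#' @param freq_keywords from [read_frequency_keywords()].
#' @param step_rules from [read_step_rules()].
#' @param study_start first study day (Date or string); prescriptions before
#'   it are OUT_OF_PERIOD and events within `window_days` of it are run-in.
#' @param study_end last study day; defaults to the latest prescription date.
#' @param window_days lookback window and run-in length in days.
#' @param output_dir optional directory; when given, the event, episode,
#'   duration-summary, transition, person-year, band-mix, retained and
#'   quarantined tables are written as CSV and the attrition report as JSON.
#' @return list with `events`, `episodes`, `durations`, `transitions`,
#'   `person_years`, `band_mix`, `retained`, `quarantined`, `report`.
#' @export
run_pipeline <- function(input,
                         catalogue = read_catalogue(),
                         exclusions = read_exclusion_rules(),
                         freq_keywords = read_frequency_keywords(),
                         step_rules = read_step_rules(),
                         study_start,
                         study_end = NULL,
                         window_days = 120,
                         output_dir = NULL) {
  input <- tibble::as_tibble(input)
  for (col in c("dispensed_date", "bnf_code", "formulation",
                "prescribed_quantity", "dispensed_quantity", "dose_text")) {
    if (!col %in% names(input)) input[[col]] <- NA
  }
  stopifnot(all(c("patient_id", "prescribed_date", "medication_name") %in% names(input)))
  total_input <- nrow(input)
  study_start <- as.Date(study_start)

  dates <- suppressWarnings(as.Date(input$prescribed_date))
  malformed <- is.na(dates) | is.na(input$patient_id) |
    is.na(input$medication_name) | !nzchar(trimws(as.character(input$medication_name)))
  quarantined <- input[malformed, , drop = FALSE]
  quarantined$quarantine_reason <- if (nrow(quarantined) > 0) "MALFORMED_ROW" else character(0)
  work <- input[!malformed, , drop = FALSE]
  dates <- dates[!malformed]
  if (is.null(study_end)) {
    study_end <- if (length(dates) > 0) max(dates) else study_start
  }
  study_end <- as.Date(study_end)

  name_txts <- norm_text(work$medication_name)
  dose_txts <- norm_text(ifelse(is.na(work$dose_text), "", as.character(work$dose_text)))
  form_txts <- norm_text(ifelse(is.na(work$formulation), "", as.character(work$formulation)))

  idx <- match_medication_idx(work$medication_name, catalogue)
  classes <- catalogue$class[idx]

  reason <- exclusion_reasons_vec(dates, name_txts, form_txts, dose_txts,
                                  classes, exclusions, c(study_start, study_end))
  # no-match outranks the rules that presuppose a matched entry
  no_match <- is.na(idx)
  pre_match <- !is.na(reason) & reason %in% c("OUT_OF_PERIOD", "DELETED")
  reason[!pre_match & no_match] <- "NO_MATCH"

  keep <- is.na(reason)
  retained <- work[keep, , drop = FALSE]
  retained$prescribed_date <- dates[keep]
  retained$med_key <- catalogue$generic_name[idx[keep]]
  retained$class <- classes[keep]
  retained$inhaler_type <- catalogue$inhaler_type[idx[keep]]
  ridx <- idx[keep]
  rname <- name_txts[keep]
  rdose <- dose_txts[keep]
  rform <- form_txts[keep]

  # corticosteroid solutions are not inhaled ICS
  is_ics <- retained$class == "ICS"
  sol_kw <- vapply(seq_len(nrow(retained)), function(i) {
    is_ics[i] && (identical(rform[i], "SOL") ||
                    any(vapply(solution_keywords, function(k) {
                      grepl(k, rdose[i], fixed = TRUE) || grepl(k, rname[i], fixed = TRUE)
                    }, logical(1))))
  }, logical(1))
  retained$class[sol_kw] <- "ORAL_OR_NEB_STEROID"

  # free-text extraction: frequency and quantity from the dose directions,
  # strength from the dose directions falling back to the medication name
  is_combo <- retained$class == "ICS_LABA"
  retained$frequency_per_day <- extract_frequency_vec(rdose, freq_keywords)
  retained$quantity_per_dose <- extract_quantity_vec(rdose)
  s1 <- extract_strength_vec(rdose, is_combo)
  s2 <- extract_strength_vec(rname, is_combo)
  use2 <- is.na(s1$strength_mcg)
  retained$strength_mcg <- ifelse(use2, s2$strength_mcg, s1$strength_mcg)
  retained$laba_component_mcg <- ifelse(use2, s2$laba_component_mcg,
                                        s1$laba_component_mcg)
  retained <- impute_by_mode(retained)

  # licensed-strength validation (exact membership, post-imputation)
  lic <- catalogue$strengths[ridx]
  out_of_range <- vapply(seq_len(nrow(retained)), function(i) {
    s <- retained$strength_mcg[i]
    !is.na(s) && length(lic[[i]]) > 0 && !(s %in% lic[[i]])
  }, logical(1))
  excl_strength <- retained[out_of_range, , drop = FALSE]
  retained <- retained[!out_of_range, , drop = FALSE]
  ridx <- ridx[!out_of_range]

  retained$daily_dose_mcg <- daily_dose(retained$frequency_per_day,
                                        retained$quantity_per_dose,
                                        retained$strength_mcg)
  ics_type <- retained$class %in% ics_classes
  retained$band <- NA_character_
  bandable <- ics_type & !is.na(retained$daily_dose_mcg)
  if (any(bandable)) {
    retained$band[bandable] <- band_daily_dose_vec(
      retained$daily_dose_mcg[bandable],
      catalogue$band_low[ridx[bandable]],
      catalogue$band_medium[ridx[bandable]],
      catalogue$band_high[ridx[bandable]]
    )
  }
  # an ICS record with no computable daily dose cannot be banded: quarantine
  undosed <- ics_type & is.na(retained$daily_dose_mcg)
  if (any(undosed)) {
    q2 <- retained[undosed, names(input), drop = FALSE]
    q2$quarantine_reason <- "ICS_DOSE_UNPARSEABLE"
    quarantined <- dplyr::bind_rows(quarantined, q2)
    retained <- retained[!undosed, , drop = FALSE]
  }

  excluded_counts <- table(factor(reason[!is.na(reason)], exclusion_reason_levels))
  excluded_counts["STRENGTH_OUT_OF_RANGE"] <- nrow(excl_strength)

  # corticosteroid solutions are retained (and counted) but are neither
  # event-generating nor part of the inhaled regimen
  regimen_input <- retained[retained$class != "ORAL_OR_NEB_STEROID", , drop = FALSE]
  events_all <- build_event_table(regimen_input, step_rules, window_days)
  events <- apply_run_in(events_all, study_start, window_days)

  episodes <- build_episode_table(events)
  durations <- summarise_durations(episodes)
  transitions <- transition_matrix(episodes, exclude_step0 = TRUE)
  person_years <- if (nrow(events) > 0) person_year_summary(events) else
    list(per_year = tibble::tibble(), aggregate = tibble::tibble(person_years = 0L))
  band_mix <- summarise_band_mix(retained)

  report <- list(
    total_input = total_input,
    excluded = as.list(as.integer(excluded_counts)) |>
      stats::setNames(names(excluded_counts)),
    retained = nrow(retained),
    quarantined = nrow(quarantined),
    oral_or_neb_steroid = sum(retained$class == "ORAL_OR_NEB_STEROID"),
    events_after_condensing = nrow(events_all),
    events_after_run_in = nrow(events),
    unique_patients = length(unique(events$patient_id))
  )
  stopifnot(report$total_input ==
              report$retained + sum(unlist(report$excluded)) + report$quarantined)

  result <- list(events = events, episodes = episodes, durations = durations,
                 transitions = transitions, person_years = person_years,
                 band_mix = band_mix, retained = retained,
                 quarantined = quarantined, report = report)
  if (!is.null(output_dir)) write_pipeline_outputs(result, output_dir)
  result
}

write_pipeline_outputs <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(x, name) readr::write_csv(x, file.path(output_dir, name))
  out(result$events, "events.csv")
  out(result$episodes, "episodes.csv")
  out(result$durations$by_step, "duration_summary_by_step.csv")
  out(result$durations$by_direction, "duration_summary_by_direction.csv")
  out(result$transitions$long, "transitions.csv")
  if (nrow(result$person_years$per_year) > 0) {
    out(result$person_years$per_year, "person_years.csv")
  }
  out(result$band_mix, "band_mix.csv")
  out(result$retained, "retained_prescriptions.csv")
  out(result$quarantined, "quarantined.csv")
  jsonlite::write_json(result$report, file.path(output_dir, "attrition_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(result)
}

#' Dose-band mix by medication type
#'
#' Proportion of banded ICS-type prescriptions in each dose category, per
#' medication type; proportions sum to one within a type.
#'
#' @param retained retained prescription table with `med_key` and `band`.
#' @return tibble: `med_key`, `band`, `n`, `proportion`.
#' @export
summarise_band_mix <- function(retained) {
  banded <- retained[!is.na(retained$band), c("med_key", "band")]
  if (nrow(banded) == 0) {
    return(tibble::tibble(med_key = character(0), band = character(0),
                          n = integer(0), proportion = numeric(0)))
  }
  banded |>
    dplyr::count(.data$med_key, .data$band) |>
    dplyr::group_by(.data$med_key) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Usage fraction captured as continuation by the lookback window
#'
#' A canister holding `canister_doses` puffs, prescribed at
#' `puffs_per_dose` puffs `frequency_per_day` times a day, lasts
#' `canister_doses / (puffs_per_dose * frequency_per_day)` days at full use.
#' The fraction of full usage at which one canister stretches over the whole
#' lookback window is that duration divided by the window length: with the
#' typical 120-dose canister at two puffs twice daily and a 120-day window,
#' usage down to 25% is still captured as continuous treatment.
#'
#' @param canister_doses puffs per canister.
#' @param puffs_per_dose puffs per dose time.
#' @param frequency_per_day dose times per day.
#' @param window_days lookback window length.
#' @return the usage fraction (0-1).
#' @export
#' @examples
#' continuation_capture_fraction()  # 0.25
continuation_capture_fraction <- function(canister_doses = 120,
                                          puffs_per_dose = 2,
                                          frequency_per_day = 2,
                                          window_days = 120) {
  days_at_full_use <- canister_doses / (puffs_per_dose * frequency_per_day)
  days_at_full_use / window_days
}
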