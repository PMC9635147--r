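#' Treatment regimens over a 120-day lookback window
#'
#' A regimen is the combination of controller therapies prescribed within the
#' lookback window ending on a prescription event: the ICS dose band (NONE /
#' LOW / MEDIUM / HIGH / UNKNOWN) plus the set of non-ICS controller classes
#' (LABA, LTRA, theophylline, other controllers). SABA is a reliever: it never
#' joins the add-on set and only marks the SABA-only regimen when nothing else
#' is in the window. Combination ICS+LABA inhalers contribute both their ICS
#' component (to banding) and LABA (to the add-on set).
#'
#' @name regimen_builder
NULL

#' Canonical regimen label
#'
#' @param ics_band one of NONE/LOW/MEDIUM/HIGH/UNKNOWN.
#' @param addons character vector over LABA/LTRA/THEOPHYLLINE/OTHER_CONTROLLER.
#' @param saba_only logical; only SABA in the window.
#' @return a label such as `"High-strength ICS + LABA + LTRA"` or `"SABA"`.
#' @export
regimen_label <- function(ics_band, addons = character(0), saba_only = FALSE) {
  addon_names <- c(LABA = "LABA", LTRA = "LTRA",
                   THEOPHYLLINE = "Theophylline",
                   OTHER_CONTROLLER = "Other controller")
  addons <- intersect(names(addon_names), addons)
  if (saba_only) return("SABA")
  parts <- character(0)
  if (ics_band != "NONE") {
    strength <- c(LOW = "Low", MEDIUM = "Medium", HIGH = "High",
                  UNKNOWN = "Unknown")[[ics_band]]
    parts <- paste0(strength, "-strength ICS")
  }
  parts <- c(parts, unname(addon_names[addons]))
  if (length(parts) == 0) return("No controller")
  paste(parts, collapse = " + ")
}

#' Construct a regimen object
#'
#' @inheritParams regimen_label
#' @return list with fields `ics_band`, `addons`, `saba_only`, `label`.
#' @export
new_regimen <- function(ics_band, addons = character(0), saba_only = FALSE) {
  ics_band <- match.arg(ics_band, band_levels)
  addons <- sort(unique(intersect(addons, addon_classes)))
  if (saba_only && (ics_band != "NONE" || length(addons) > 0)) {
    stop("saba_only requires no ICS band and no add-ons")
  }
  list(ics_band = ics_band, addons = addons, saba_only = saba_only,
       label = regimen_label(ics_band, addons, saba_only))
}

#' Condense same-day prescriptions to one candidate event per date
#'
#' Multiple prescriptions on one day collapse to a single candidate
#' prescription event; all medications prescribed on that day still
#' contribute to the lookback window content at that and later events.
#'
#' @param records retained prescriptions for one or more patients, with
#'   columns `patient_id` and `prescribed_date`.
#' @return tibble of distinct (`patient_id`, `event_date`) rows, ordered.
#' @export
condense_same_day <- function(records) {
  records |>
    dplyr::distinct(.data$patient_id, event_date = as.Date(.data$prescribed_date)) |>
    dplyr::arrange(.data$patient_id, .data$event_date)
}

# most-recent daily dose per ICS-containing product in the window, banded on
# the product's own thresholds; the regimen band is the maximum across
# products (UNKNOWN dominates: it denotes a dose above the high range)
window_ics_band <- function(win) {
  sel <- win$class %in% ics_classes & !is.na(win$band)
  if (!any(sel)) return("NONE")
  key <- win$med_key[sel]
  date <- as.numeric(win$prescribed_date[sel])
  bnum <- match(win$band[sel], band_levels)
  best <- 1L
  for (k in unique(key)) {
    i <- key == k
    recent <- i & date == max(date[i])
    best <- max(best, max(bnum[recent]))
  }
  band_levels[best]
}

#' Build the regimen active at an index date
#'
#' The window is the `window_days`-day interval ending on (and including) the
#' index date. Add-ons are the non-ICS controller classes with at least one
#' prescription in the window. The ICS band comes from banding each distinct
#' ICS-containing product's most recent daily dose on its own thresholds and
#' taking the maximum band across products.
#'
#' @param history one patient's retained prescriptions: columns
#'   `prescribed_date`, `med_key`, `class`, `band` (per-record dose band,
#'   `NA` for non-ICS records).
#' @param index_date the prescription event date.
#' @param window_days lookback length in days (default 120).
#' @return a regimen (see [new_regimen()]), or `NULL` when the window holds
#'   no prescriptions.
#' @export
build_regimen <- function(history, index_date, window_days = 120) {
  stopifnot(window_days > 0)
  index_date <- as.Date(index_date)
  d <- as.Date(history$prescribed_date)
  win <- history[d > index_date - window_days & d <= index_date, ]
  if (nrow(win) == 0) return(NULL)
  band <- window_ics_band(win)
  addons <- sort(unique(intersect(win$class, addon_classes)))
  if ("ICS_LABA" %in% win$class) addons <- sort(unique(c(addons, "LABA")))
  saba_only <- band == "NONE" && length(addons) == 0 && all(win$class == "SABA")
  new_regimen(band, addons, saba_only)
}

#' Drop events inside the run-in period
#'
#' The first `window_days` days of the study are a run-in during which
#' staggered refills of a regimen's components are still accumulating, so a
#' lookback window there under-covers the true regimen; events dated before
#' `study_start + window_days` are removed.
#'
#' @param events tibble with `event_date`.
#' @param study_start first day of the study period (Date).
#' @param window_days run-in length, equal to the lookback window (120).
#' @return filtered events.
#' @export
apply_run_in <- function(events, study_start, window_days = 120) {
  events[as.Date(events$event_date) >= as.Date(study_start) + window_days, , drop = FALSE]
}

#' Build the per-event regimen table for a cohort
#'
#' Condenses same-day prescriptions, evaluates the lookback regimen at every
#' prescription event, and classifies each regimen to a treatment step.
#'
#' @param retained retained prescription table: `patient_id`,
#'   `prescribed_date`, `med_key`, `class`, `band`.
#' @param step_rules step rule table from [read_step_rules()].
#' @param window_days lookback length in days.
#' @return tibble: `patient_id`, `event_date`, `ics_band`, `addons`
#'   (plus-separated), `saba_only`, `regimen`, `step`.
#' @export
build_event_table <- function(retained, step_rules = read_step_rules(),
                              window_days = 120) {
  events <- condense_same_day(retained)
  if (nrow(events) == 0) {
    return(tibble::tibble(patient_id = character(0), event_date = as.Date(character(0)),
                          ics_band = character(0), addons = character(0),
                          saba_only = logical(0), regimen = character(0),
                          step = integer(0)))
  }
  retained$prescribed_date <- as.Date(retained$prescribed_date)
  out <- lapply(split(events, events$patient_id), function(ev) {
    hist <- retained[retained$patient_id == ev$patient_id[1], ]
    regs <- lapply(ev$event_date, function(d) build_regimen(hist, d, window_days))
    keep <- !vapply(regs, is.null, logical(1))
    ev <- ev[keep, ]
    regs <- regs[keep]
    ev$ics_band <- vapply(regs, `[[`, character(1), "ics_band")
    ev$addons <- vapply(regs, function(r) paste(r$addons, collapse = "+"), character(1))
    ev$saba_only <- vapply(regs, `[[`, logical(1), "saba_only")
    ev$regimen <- vapply(regs, `[[`, character(1), "label")
    ev$step <- vapply(regs, function(r) {
      classify_step_core(r$ics_band, length(r$addons), step_rules)
    }, integer(1))
    ev
  })
  dplyr::bind_rows(out) |> dplyr::arrange(.data$patient_id, .data$event_date)
}
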