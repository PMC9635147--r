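#' Medication catalogue and exclusion rules
#'
#' The catalogue maps medication names and brand names to a medication class
#' (ICS, ICS_LABA, LABA, SABA, LTRA, THEOPHYLLINE, OTHER_CONTROLLER,
#' ORAL_OR_NEB_STEROID), an inhaler type (DPI/MDI/NA), the unit strengths
#' licensed for asthma, and the low/medium/high daily-dose band thresholds
#' (micrograms per day) used by [derive_band_ranges()]. Discontinued brands
#' (AeroBec, Beclazone, Filair) appear as their own rows carrying the
#' thresholds of the parent drug and inhaler type, so banding groups them with
#' the parent drug.
#'
#' The shipped default catalogue is a reconstruction assembled from
#' UK-licensed asthma medications and the 2019 BTS/SIGN adult dose tables; it
#' is editable data, not code, and users should replace it with their own
#' lookup table where local formularies differ.
#'
#' @param path CSV file with columns `generic_name`, `class`, `brand_names`
#'   (semicolon-separated), `inhaler_type`, `licensed_strengths_mcg`
#'   (semicolon-separated), `band_low`, `band_medium`, `band_high`.
#' @return A tibble with one row per catalogue entry; `brands` and
#'   `strengths` are list-columns of character/numeric vectors.
#' @export
read_catalogue <- function(path = default_catalogue_path()) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  needed <- c("generic_name", "class", "brand_names", "inhaler_type",
              "licensed_strengths_mcg", "band_low", "band_medium", "band_high")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop("catalogue file lacks columns: ", paste(missing, collapse = ", "))
  }
  cat <- tibble::tibble(
    generic_name = norm_text(raw$generic_name),
    class = toupper(trimws(raw$class)),
    brands = lapply(raw$brand_names, function(b) norm_text(split_semi(b))),
    inhaler_type = toupper(trimws(ifelse(is.na(raw$inhaler_type), "NA", raw$inhaler_type))),
    strengths = lapply(raw$licensed_strengths_mcg, split_semi_num),
    band_low = suppressWarnings(as.numeric(raw$band_low)),
    band_medium = suppressWarnings(as.numeric(raw$band_medium)),
    band_high = suppressWarnings(as.numeric(raw$band_high))
  )
  validate_catalogue(cat)
  cat
}

#' @rdname read_catalogue
#' @export
default_catalogue_path <- function() {
  sys_file("extdata", "medication_catalogue.csv")
}

medication_classes <- c("ICS", "ICS_LABA", "LABA", "SABA", "LTRA",
                        "THEOPHYLLINE", "OTHER_CONTROLLER", "ORAL_OR_NEB_STEROID")
ics_classes <- c("ICS", "ICS_LABA")
addon_classes <- c("LABA", "LTRA", "THEOPHYLLINE", "OTHER_CONTROLLER")

validate_catalogue <- function(cat) {
  if (anyDuplicated(cat$generic_name)) {
    stop("duplicate generic_name in catalogue")
  }
  bad_class <- setdiff(unique(cat$class), medication_classes)
  if (length(bad_class) > 0) {
    stop("unknown medication class: ", paste(bad_class, collapse = ", "))
  }
  if (!all(cat$inhaler_type %in% c("DPI", "MDI", "NA"))) {
    stop("inhaler_type must be DPI, MDI or NA")
  }
  for (i in seq_len(nrow(cat))) {
    s <- cat$strengths[[i]]
    if (length(s) > 0 && any(s <= 0)) {
      stop("non-positive licensed strength for ", cat$generic_name[i])
    }
    if (cat$class[i] %in% ics_classes) {
      thr <- c(cat$band_low[i], cat$band_medium[i], cat$band_high[i])
      if (all(is.na(thr))) {
        stop("ICS entry without any band threshold: ", cat$generic_name[i])
      }
      present <- thr[!is.na(thr)]
      if (any(diff(present) <= 0)) {
        stop("band thresholds not strictly increasing for ", cat$generic_name[i])
      }
    }
  }
  invisible(cat)
}

#' @param rules_path CSV file with columns `keyword`, `applies_to`
#'   (DOSE_TEXT, MEDICATION_NAME, FORMULATION or BRAND) and `reason`
#'   (NON_ASTHMA_INDICATION, FORMULATION_EXCLUDED, NON_ASTHMA_BRAND, DELETED
#'   or OUT_OF_PERIOD).
#' @rdname read_catalogue
#' @export
read_exclusion_rules <- function(rules_path = default_exclusions_path()) {
  raw <- readr::read_csv(rules_path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  rules <- tibble::tibble(
    keyword = norm_text(raw$keyword),
    applies_to = toupper(trimws(raw$applies_to)),
    reason = toupper(trimws(raw$reason))
  )
  if (any(!nzchar(rules$keyword))) stop("empty exclusion keyword")
  ok_to <- c("DOSE_TEXT", "MEDICATION_NAME", "FORMULATION", "BRAND")
  ok_reason <- c("NON_ASTHMA_INDICATION", "FORMULATION_EXCLUDED",
                 "NON_ASTHMA_BRAND", "DELETED", "OUT_OF_PERIOD")
  if (!all(rules$applies_to %in% ok_to)) stop("invalid applies_to in exclusion rules")
  if (!all(rules$reason %in% ok_reason)) stop("invalid reason in exclusion rules")
  rules
}

#' @rdname read_catalogue
#' @export
default_exclusions_path <- function() {
  sys_file("extdata", "exclusion_keywords.csv")
}

#' Match a medication name against the catalogue
#'
#' A catalogue entry matches when its generic name or any of its brand names
#' occurs as a substring of the upper-cased, whitespace-normalised medication
#' name. Exactly one entry may match; two distinct matching entries indicate
#' overlapping catalogue keys (a catalogue defect) and raise an error rather
#' than being silently resolved.
#'
#' @param name_text medication name as recorded in the prescription (free text).
#' @param catalogue tibble from [read_catalogue()].
#' @return The matching one-row tibble, or `NULL` when no entry matches.
#' @export
#' @examples
#' cat <- read_catalogue()
#' match_medication("Clenil Modulite 100mcg inhaler", cat)$class
match_medication <- function(name_text, catalogue) {
  if (is.na(name_text) || !nzchar(trimws(name_text))) {
    stop("medication name text must be non-empty")
  }
  txt <- norm_text(name_text)
  hit <- vapply(seq_len(nrow(catalogue)), function(i) {
    keys <- c(catalogue$generic_name[i], catalogue$brands[[i]])
    any(vapply(keys, function(k) grepl(k, txt, fixed = TRUE), logical(1)))
  }, logical(1))
  n <- sum(hit)
  if (n == 0) return(NULL)
  if (n > 1) {
    stop("ambiguous medication match for '", name_text, "': ",
         paste(catalogue$generic_name[hit], collapse = ", "),
         " (overlapping catalogue keys)")
  }
  catalogue[hit, ]
}

# vectorised matcher used by the pipeline: returns integer row index or NA
match_medication_idx <- function(name_texts, catalogue) {
  txts <- norm_text(name_texts)
  keysets <- lapply(seq_len(nrow(catalogue)), function(i) {
    c(catalogue$generic_name[i], catalogue$brands[[i]])
  })
  hitmat <- vapply(keysets, function(keys) {
    Reduce(`|`, lapply(keys, function(k) grepl(k, txts, fixed = TRUE)))
  }, logical(length(txts)))
  hitmat <- matrix(hitmat, nrow = length(txts))
  nhit <- rowSums(hitmat)
  amb <- which(nhit > 1)
  if (length(amb) > 0) {
    i <- amb[1]
    stop("ambiguous medication match for '", name_texts[i], "': ",
         paste(catalogue$generic_name[hitmat[i, ]], collapse = ", "))
  }
  out <- rep(NA_integer_, length(txts))
  got <- nhit == 1
  out[got] <- apply(hitmat[got, , drop = FALSE], 1, which)
  out
}

# keyword present in normalised text, on word boundaries
keyword_hit <- function(keywords, txt) {
  if (length(keywords) == 0 || is.na(txt) || !nzchar(txt)) return(FALSE)
  any(vapply(keywords,
             function(k) grepl(paste0("\\b", k, "\\b"), txt), logical(1)))
}

#' Apply exclusion rules to a matched prescription record
#'
#' Dispositions are checked in a fixed precedence so that attrition counts are
#' well defined: prescription date outside the study period, then
#' deletion-note keywords, then formulation exclusions (ICS-type entries with
#' spray/drop-like formulations, used outside asthma e.g. for allergic
#' rhinitis), then non-asthma indication keywords in the dose text or
#' medication name, then non-asthma brand keywords. The first matching rule
#' wins.
#'
#' @param record a one-row data frame / list with fields `prescribed_date`,
#'   `medication_name`, `formulation`, `dose_text`.
#' @param entry the catalogue entry the record matched.
#' @param rules tibble from [read_exclusion_rules()].
#' @param study_period length-2 Date vector `c(start, end)` inclusive.
#' @return `list(keep = TRUE)` or `list(keep = FALSE, reason = <reason>)`.
#' @export
apply_exclusions <- function(record, entry, rules, study_period) {
  if (is.na(record$prescribed_date)) stop("record has no prescription date")
  reason <- exclusion_reasons_vec(
    dates = as.Date(record$prescribed_date),
    name_txts = norm_text(record$medication_name %||% ""),
    form_txts = norm_text(record$formulation %||% ""),
    dose_txts = norm_text(record$dose_text %||% ""),
    classes = entry$class,
    rules = rules, study_period = study_period
  )
  if (is.na(reason)) list(keep = TRUE) else list(keep = FALSE, reason = reason)
}

# vectorised keyword hit: any keyword present (word-bounded) in each text
keyword_hit_vec <- function(keywords, txts) {
  if (length(keywords) == 0) return(rep(FALSE, length(txts)))
  hit <- rep(FALSE, length(txts))
  for (k in keywords) {
    hit <- hit | grepl(paste0("\\b", k, "\\b"), txts)
  }
  hit & nzchar(txts)
}

# vectorised disposition core shared by apply_exclusions and the pipeline;
# texts must already be normalised; returns the exclusion reason or NA (keep)
exclusion_reasons_vec <- function(dates, name_txts, form_txts, dose_txts,
                                  classes, rules, study_period) {
  n <- length(dates)
  reason <- rep(NA_character_, n)
  kw <- function(to, why) rules$keyword[rules$applies_to == to & rules$reason == why]
  assign_if <- function(reason, cond, why) {
    ifelse(is.na(reason) & cond, why, reason)
  }
  reason <- assign_if(reason, dates < study_period[1] | dates > study_period[2],
                      "OUT_OF_PERIOD")
  reason <- assign_if(reason,
                      keyword_hit_vec(kw("DOSE_TEXT", "DELETED"), dose_txts) |
                        keyword_hit_vec(kw("MEDICATION_NAME", "DELETED"), name_txts),
                      "DELETED")
  reason <- assign_if(reason,
                      classes %in% ics_classes &
                        keyword_hit_vec(kw("FORMULATION", "FORMULATION_EXCLUDED"),
                                        form_txts),
                      "FORMULATION_EXCLUDED")
  ind <- kw("DOSE_TEXT", "NON_ASTHMA_INDICATION")
  ind_name <- kw("MEDICATION_NAME", "NON_ASTHMA_INDICATION")
  reason <- assign_if(reason,
                      keyword_hit_vec(ind, dose_txts) |
                        keyword_hit_vec(c(ind, ind_name), name_txts),
                      "NON_ASTHMA_INDICATION")
  brand <- c(kw("BRAND", "NON_ASTHMA_BRAND"), kw("MEDICATION_NAME", "NON_ASTHMA_BRAND"))
  reason <- assign_if(reason, keyword_hit_vec(brand, name_txts), "NON_ASTHMA_BRAND")
  reason
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

solution_keywords <- c("SACHET", "RESPULE", "NEB", "VIAL", "AMPOULE")

#' Reclassify corticosteroid solutions
#'
#' Corticosteroid solutions (nebuliser and oral preparations) are
#' distinguished from inhaled ICS by the recorded formulation code "SOL", or
#' by the presence of any of SACHET, RESPULE, NEB, VIAL or AMPOULE in the dose
#' directions or medication name (plain substring match, so NEBULISER and
#' RESPULES also trigger). Only entries of class ICS are ever reclassified.
#'
#' @inheritParams apply_exclusions
#' @return The medication class for the record: `"ORAL_OR_NEB_STEROID"` or the
#'   entry's own class.
#' @export
reclassify_solution <- function(record, entry) {
  if (entry$class != "ICS") return(entry$class)
  form_txt <- norm_text(record$formulation %||% "")
  combined <- paste(norm_text(record$dose_text %||% ""),
                    norm_text(record$medication_name %||% ""))
  if (identical(form_txt, "SOL") ||
      any(vapply(solution_keywords, function(k) grepl(k, combined, fixed = TRUE),
                 logical(1)))) {
    return("ORAL_OR_NEB_STEROID")
  }
  entry$class
}
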