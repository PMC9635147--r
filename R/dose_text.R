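#' Free-text dose instruction parsing
#'
#' Prescribed daily dose is the product of three quantities recovered from the
#' prescription's free-text fields: the number of dose times per day (dose
#' frequency), the number of puffs taken at each dose time (dose quantity),
#' and the strength of each puff in micrograms. Each is extracted by the
#' rule set below; values that cannot be extracted are imputed with the most
#' common (mode) value for the same medication type by [impute_by_mode()].
#'
#' @name dose_text_extraction
NULL

# strength value lists, searched in exactly this order (descending), so that
# e.g. "250MCG" is never read as "50MCG" and "0.5MG" never as "5MG"
mcg_values <- c(10000, 5000, 4000, 2000, 1000, 500, 400, 320, 250, 200,
                184, 160, 125, 100, 92, 80, 65, 50)
mg_values <- c(0.5, 20, 10, 5, 4, 2, 1)

#' Read the dose-frequency keyword table
#'
#' @param path CSV with columns `phrase` and `doses_per_day`. The shipped
#'   default covers the common prescribing phrasings (ONCE, TWICE, 3/THREE
#'   TIMES, 4/FOUR TIMES, MORNING AND NIGHT) and Latin abbreviations
#'   (OD, BD, TDS, QDS, NOCTE, MANE).
#' @return tibble ordered longest phrase first (match precedence).
#' @export
read_frequency_keywords <- function(path = default_frequency_keywords_path()) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(phrase = readr::col_character(),
                                                 doses_per_day = readr::col_integer()))
  raw$phrase <- norm_text(raw$phrase)
  if (any(!nzchar(raw$phrase)) || any(raw$doses_per_day < 1)) {
    stop("invalid frequency keyword table")
  }
  raw[order(-nchar(raw$phrase)), ]
}

#' @rdname read_frequency_keywords
#' @export
default_frequency_keywords_path <- function() {
  sys_file("extdata", "frequency_keywords.csv")
}

# vectorised frequency extraction; phrases matched on word boundaries,
# longest phrase first
extract_frequency_vec <- function(dose_texts, keywords) {
  txts <- norm_text(dose_texts)
  out <- rep(NA_integer_, length(txts))
  for (i in seq_len(nrow(keywords))) {
    todo <- is.na(out) & nzchar(txts)
    if (!any(todo)) break
    pat <- paste0("\\b", keywords$phrase[i], "\\b")
    hit <- grepl(pat, txts[todo])
    out[todo][hit] <- keywords$doses_per_day[i]
  }
  out
}

#' Extract dose frequency (dose times per day) from dose directions
#'
#' Returns the daily frequency for the first matching keyword phrase
#' (longest phrase first), or `NA` when no phrase occurs.
#'
#' @param dose_text free-text dose directions.
#' @param keywords tibble from [read_frequency_keywords()].
#' @return integer doses per day, or `NA_integer_`.
#' @export
#' @examples
#' extract_frequency("TAKE TWO PUFFS TWICE DAILY")
extract_frequency <- function(dose_text, keywords = read_frequency_keywords()) {
  extract_frequency_vec(dose_text, keywords)
}

number_words <- c(ONE = 1L, TWO = 2L, THREE = 3L, FOUR = 4L,
                  "1" = 1L, "2" = 2L, "3" = 3L, "4" = 4L)

# quantity rule: the numbers one..four (numerals or words) preceded by TAKE or
# INHALE, or followed by DAILY, AT, TO BE TAKEN, or PUF (single 'f', so PUFF /
# PUFS / PUFFS all match) or P-then-space (shorthand for puffs)
quantity_pattern <- paste0(
  "\\b(?:TAKE|INHALE)\\s+(?<pre>ONE|TWO|THREE|FOUR|[1-4])\\b",
  "|\\b(?<post>ONE|TWO|THREE|FOUR|[1-4])\\s*(?:DAILY\\b|TO BE TAKEN\\b|AT\\b|PUF|P\\s)"
)

extract_quantity_vec <- function(dose_texts) {
  txts <- norm_text(dose_texts)
  out <- rep(NA_integer_, length(txts))
  m <- regexpr(quantity_pattern, txts, perl = TRUE)
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  hit <- which(m > 0)
  for (i in hit) {
    grp <- if (cs[i, "pre"] > 0) "pre" else "post"
    tok <- substr(txts[i], cs[i, grp], cs[i, grp] + cl[i, grp] - 1L)
    out[i] <- number_words[[tok]]
  }
  out
}

#' Extract dose quantity (puffs per dose) from dose directions
#'
#' @inheritParams extract_frequency
#' @return integer puffs per dose (1-4), or `NA_integer_`. Numbers above four
#'   are outside the rule and fall through to imputation.
#' @export
#' @examples
#' extract_quantity("2 PUFS AT NIGHT")
extract_quantity <- function(dose_text) {
  extract_quantity_vec(dose_text)
}

# allow an optional thousands space ("10 000MCG") for values >= 1000
value_regex <- function(v) {
  s <- format(v, scientific = FALSE, trim = TRUE)
  if (v >= 1000) {
    sub("^([0-9]+)([0-9]{3})$", "\\1 ?\\2", s)
  } else {
    gsub(".", "\\.", s, fixed = TRUE)
  }
}

# one strength value, not preceded by a digit or decimal point, followed by a
# unit token (optionally space-separated); combination products may instead be
# followed by "/" and the LABA component
strength_scan <- function(txts, values, units, allow_slash, scale) {
  strength <- rep(NA_real_, length(txts))
  laba <- rep(NA_real_, length(txts))
  unit_alt <- paste(units, collapse = "|")
  for (v in values) {
    todo <- which(is.na(strength) & nzchar(txts))
    if (length(todo) == 0) break
    suffix <- if (allow_slash) {
      paste0("(?: ?(?:", unit_alt, ")|/(?<laba>[0-9]+(?:\\.[0-9]+)?))")
    } else {
      paste0(" ?(?:", unit_alt, ")")
    }
    pat <- paste0("(?<![0-9.])", value_regex(v), suffix)
    m <- regexpr(pat, txts[todo], perl = TRUE)
    hit <- m > 0
    if (!any(hit)) next
    strength[todo[hit]] <- v * scale
    if (allow_slash) {
      cs <- attr(m, "capture.start")
      cl <- attr(m, "capture.length")
      got_laba <- hit & cs[, "laba"] > 0
      if (any(got_laba)) {
        idx <- which(got_laba)
        laba[todo[idx]] <- as.numeric(substr(txts[todo[idx]],
                                             cs[idx, "laba"],
                                             cs[idx, "laba"] + cl[idx, "laba"] - 1L))
      }
    }
  }
  list(strength = strength, laba = laba)
}

extract_strength_vec <- function(texts, is_combo) {
  txts <- norm_text(texts)
  is_combo <- rep_len(is_combo, length(txts))
  strength <- rep(NA_real_, length(txts))
  laba <- rep(NA_real_, length(txts))
  for (combo in c(TRUE, FALSE)) {
    sel <- which(is_combo == combo)
    if (length(sel) == 0) next
    mcg <- strength_scan(txts[sel], mcg_values, c("MCG", "MICROGRAMS?"),
                         allow_slash = combo, scale = 1)
    strength[sel] <- mcg$strength
    laba[sel] <- mcg$laba
    miss <- sel[is.na(strength[sel])]
    if (length(miss) > 0) {
      mg <- strength_scan(txts[miss], mg_values, c("MG", "MILLIGRAMS?"),
                          allow_slash = FALSE, scale = 1000)
      strength[miss] <- mg$strength
    }
  }
  list(strength_mcg = strength, laba_component_mcg = laba)
}

#' Extract medication strength from free text
#'
#' Searches a fixed list of microgram values (descending, so longer values are
#' found before their suffixes), each followed by "MCG" or "MICROGRAM" with or
#' without a space; if none matches, a fixed list of milligram values
#' (0.5 searched before the integers) followed by "MG" or "MILLIGRAM",
#' converted to micrograms. For combination ICS+LABA products the value may
#' instead be followed by "/" and the LABA component strength (e.g.
#' "250/25"), in which case the ICS component is the value before the slash.
#'
#' @param text free text to scan (dose directions and/or medication name).
#' @param is_combo whether the medication is a combination ICS+LABA product.
#' @return list with `strength_mcg` and `laba_component_mcg` (both `NA` when
#'   nothing matches).
#' @export
#' @examples
#' extract_strength("FLUTICASONE 250MCG INHALER")$strength_mcg
#' extract_strength("BUDESONIDE 0.5MG RESPULES")$strength_mcg
extract_strength <- function(text, is_combo = FALSE) {
  out <- extract_strength_vec(text, is_combo)
  list(strength_mcg = out$strength_mcg[1], laba_component_mcg = out$laba_component_mcg[1])
}

#' Impute missing parsed-dose components by per-medication mode
#'
#' For each medication type (catalogue entry), absent frequencies, quantities
#' and strengths are replaced by the most common observed value for that
#' medication; ties break to the smallest value, which never inflates the
#' estimated dose. Observed values are never altered. When a medication has
#' no observed value at all for a field, that field stays absent.
#'
#' @param parsed tibble with columns `med_key`, `frequency_per_day`,
#'   `quantity_per_dose`, `strength_mcg` (and optionally pre-existing
#'   `imputed_*` flags, which are ignored and recomputed).
#' @return the same tibble with absences filled and logical columns
#'   `imputed_frequency`, `imputed_quantity`, `imputed_strength`.
#' @export
impute_by_mode <- function(parsed) {
  fields <- c(frequency_per_day = "imputed_frequency",
              quantity_per_dose = "imputed_quantity",
              strength_mcg = "imputed_strength")
  for (f in names(fields)) {
    parsed[[fields[[f]]]] <- is.na(parsed[[f]])
  }
  if (nrow(parsed) == 0) return(parsed)
  for (f in names(fields)) {
    flag <- fields[[f]]
    parsed <- parsed |>
      dplyr::group_by(.data$med_key) |>
      dplyr::mutate(!!f := {
        x <- .data[[f]]
        if (any(is.na(x)) && any(!is.na(x))) {
          x[is.na(x)] <- mode_smallest(x[!is.na(x)])
        }
        x
      }) |>
      dplyr::ungroup()
    parsed[[flag]] <- parsed[[flag]] & !is.na(parsed[[f]])
    # flag stays FALSE where the value is still absent: nothing was imputed
    parsed[[flag]][is.na(parsed[[f]])] <- FALSE
  }
  parsed
}

#' Check an extracted strength against the licensed strengths for asthma
#'
#' @param entry catalogue entry (one-row tibble from [match_medication()]).
#' @param strength_mcg strength per unit in micrograms.
#' @return `TRUE` when the strength is one of the entry's licensed strengths
#'   (or when the entry lists no licensed strengths, in which case no range is
#'   configured); `FALSE` flags the record for exclusion with reason
#'   STRENGTH_OUT_OF_RANGE.
#' @export
validate_strength <- function(entry, strength_mcg) {
  stopifnot(!is.na(strength_mcg))
  licensed <- entry$strengths[[1]]
  if (length(licensed) == 0) return(TRUE)
  strength_mcg %in% licensed
}

#' Prescribed daily dose in micrograms
#'
#' Frequency times quantity times unit strength, `NA` when any component is
#' still absent after imputation.
#'
#' @param frequency_per_day doses per day.
#' @param quantity_per_dose puffs per dose.
#' @param strength_mcg micrograms per puff.
#' @return numeric micrograms per day.
#' @export
daily_dose <- function(frequency_per_day, quantity_per_dose, strength_mcg) {
  frequency_per_day * quantity_per_dose * strength_mcg
}
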