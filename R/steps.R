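#' Treatment-step decision tree
#'
#' Regimens map to BTS/SIGN treatment steps 0-4 via an ordered rule table
#' over the regimen's ICS band and add-on count: first matching rule wins.
#' The default adult tree is: no ICS component regardless of add-ons
#' (including SABA or LABA monotherapy) is Step 0; low-strength ICS alone is
#' Step 1 (the only Step-1 regimen); low ICS plus one add-on is Step 2;
#' medium ICS with at most one add-on, or low ICS with two or more add-ons,
#' is Step 3; high or unknown-band ICS, or medium ICS with two or more
#' add-ons, is Step 4. The table is data, not code, so users can align it
#' with local guideline interpretations; it is validated for totality at load
#' time, so every possible regimen receives a step and no manual assignment
#' is ever needed.
#'
#' @name step_classifier
NULL

#' Read and validate a step rule table
#'
#' @param path CSV with columns `ics_band` (semicolon-separated set of bands
#'   the rule covers), `min_addons`, `max_addons` (empty = unbounded) and
#'   `step` (0-4). A paediatric variant (one strength category down) ships
#'   alongside the adult default but is not enabled by default.
#' @param addon_classes add-on classes the regimen space ranges over, used for
#'   the totality audit.
#' @return tibble of ordered rules with attribute `"addon_classes"`.
#' @export
read_step_rules <- function(path = default_step_rules_path(),
                            addon_classes = c("LABA", "LTRA", "THEOPHYLLINE",
                                              "OTHER_CONTROLLER")) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(ics_band = readr::col_character(),
                                                 min_addons = readr::col_integer(),
                                                 max_addons = readr::col_integer(),
                                                 step = readr::col_integer()))
  rules <- tibble::tibble(
    bands = lapply(raw$ics_band, function(b) toupper(split_semi(b))),
    min_addons = raw$min_addons,
    max_addons = ifelse(is.na(raw$max_addons), .Machine$integer.max, raw$max_addons),
    step = raw$step
  )
  if (!all(unlist(rules$bands) %in% band_levels)) stop("unknown band in step rules")
  if (!all(rules$step %in% 0:4)) stop("steps must be 0-4")
  attr(rules, "addon_classes") <- addon_classes
  space <- enumerate_regimen_space(rules, addon_classes)
  step1 <- space[space$step == 1, ]
  if (nrow(step1) != 1) {
    stop("step rule table assigns ", nrow(step1),
         " regimen configurations to Step 1; exactly one (low-dose ICS alone) is expected")
  }
  rules
}

#' @rdname read_step_rules
#' @export
default_step_rules_path <- function() {
  sys_file("extdata", "step_rules_adult.csv")
}

#' @rdname read_step_rules
#' @export
paediatric_step_rules_path <- function() {
  sys_file("extdata", "step_rules_paediatric.csv")
}

classify_step_core <- function(ics_band, n_addons, rules) {
  for (i in seq_len(nrow(rules))) {
    if (ics_band %in% rules$bands[[i]] &&
        n_addons >= rules$min_addons[i] && n_addons <= rules$max_addons[i]) {
      return(rules$step[i])
    }
  }
  NA_integer_
}

#' Classify a regimen to a treatment step
#'
#' @param regimen a regimen from [new_regimen()] / [build_regimen()].
#' @param rules rule table from [read_step_rules()].
#' @return integer step 0-4.
#' @export
#' @examples
#' rules <- read_step_rules()
#' classify_step(new_regimen("MEDIUM", "LABA"), rules)  # 3
classify_step <- function(regimen, rules = read_step_rules()) {
  step <- classify_step_core(regimen$ics_band, length(regimen$addons), rules)
  if (is.na(step)) {
    stop("step rule table does not cover regimen: ", regimen$label)
  }
  step
}

#' Enumerate the full regimen configuration space
#'
#' Crosses every ICS band with every subset of the add-on classes and
#' assigns each configuration a step; errors listing the uncovered
#' configurations when the rule table is not total. This is the audit behind
#' the guarantee that the mapping needs no manual assignment.
#'
#' @inheritParams read_step_rules
#' @param rules rule table (see [read_step_rules()]).
#' @return tibble: `ics_band`, `addons` (plus-separated), `n_addons`, `step`.
#' @export
enumerate_regimen_space <- function(rules,
                                    addon_classes = attr(rules, "addon_classes")) {
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(addon_classes)))
  names(subsets) <- addon_classes
  combos <- apply(subsets, 1, function(r) addon_classes[as.logical(r)], simplify = FALSE)
  space <- expand.grid(band = band_levels, combo = seq_along(combos),
                       stringsAsFactors = FALSE)
  space <- tibble::tibble(
    ics_band = space$band,
    addons = vapply(combos[space$combo], paste, character(1), collapse = "+"),
    n_addons = lengths(combos[space$combo])
  )
  space$step <- mapply(classify_step_core, space$ics_band, space$n_addons,
                       MoreArgs = list(rules = rules))
  if (anyNA(space$step)) {
    bad <- space[is.na(space$step), ]
    stop("step rule table is not total; uncovered configurations: ",
         paste(paste0(bad$ics_band, "[", bad$addons, "]"), collapse = ", "))
  }
  space
}
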