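#' Treatment-step trajectory statistics
#'
#' Step status is observable only at prescription events, so an episode's
#' duration runs from its first event to the first event of the next episode
#' at a different step. A patient's final episode has no observed change: its
#' time to change is censored and it is excluded from duration summaries
#' (with the censored percentage disclosed per stratum).
#'
#' @name trajectory_stats
NULL

#' Build step episodes from one patient's event sequence
#'
#' Consecutive events at the same step merge into one episode. The episode
#' ends at the first event of the next different-step episode; `direction`
#' is UP or DOWN by comparison with the next step, CENSORED for the final
#' episode. Regimen changes between consecutive same-step events are counted
#' as within-step changes.
#'
#' @param events one patient's events ordered by date: columns `patient_id`,
#'   `event_date`, `step` and optionally `regimen`.
#' @return tibble of episodes: `patient_id`, `step`, `start_date`,
#'   `end_date`, `duration_days`, `next_step`, `direction`,
#'   `regimen_changes_within`.
#' @export
build_episodes <- function(events) {
  if (nrow(events) == 0) {
    return(tibble::tibble(patient_id = character(0), step = integer(0),
                          start_date = as.Date(character(0)),
                          end_date = as.Date(character(0)),
                          duration_days = integer(0), next_step = integer(0),
                          direction = character(0),
                          regimen_changes_within = integer(0)))
  }
  stopifnot(length(unique(events$patient_id)) == 1)
  events <- events[order(as.Date(events$event_date)), ]
  events <- events[!duplicated(events$event_date), ]
  dates <- as.Date(events$event_date)
  steps <- as.integer(events$step)
  regs <- if ("regimen" %in% names(events)) events$regimen else rep("", length(steps))

  run_id <- cumsum(c(TRUE, steps[-1] != steps[-length(steps)]))
  n_runs <- max(run_id)
  start <- dates[!duplicated(run_id)]
  run_step <- steps[!duplicated(run_id)]
  # within-run regimen label changes between consecutive events
  within <- vapply(seq_len(n_runs), function(r) {
    rg <- regs[run_id == r]
    if (length(rg) < 2) 0L else sum(rg[-1] != rg[-length(rg)])
  }, integer(1))
  end <- c(start[-1], dates[length(dates)])
  next_step <- c(run_step[-1], NA_integer_)
  direction <- dplyr::case_when(
    is.na(next_step) ~ "CENSORED",
    next_step > run_step ~ "UP",
    TRUE ~ "DOWN"
  )
  tibble::tibble(
    patient_id = events$patient_id[1],
    step = run_step,
    start_date = start,
    end_date = end,
    duration_days = as.integer(end - start),
    next_step = next_step,
    direction = direction,
    regimen_changes_within = within
  )
}

#' Build episodes for every patient in an event table
#'
#' @param events event table from [build_event_table()].
#' @return episode tibble (see [build_episodes()]).
#' @export
build_episode_table <- function(events) {
  if (nrow(events) == 0) return(build_episodes(events))
  dplyr::bind_rows(lapply(split(events, events$patient_id), build_episodes))
}

summarise_one <- function(dur) {
  if (length(dur) == 0) {
    return(tibble::tibble(n = 0L, median_days = NA_real_,
                          iqr_low = NA_real_, iqr_high = NA_real_))
  }
  q <- unname(quantile(dur, c(0.25, 0.5, 0.75)))
  tibble::tibble(n = length(dur), median_days = q[2], iqr_low = q[1], iqr_high = q[3])
}

#' Summarise durations until step change
#'
#' Medians and interquartile ranges of episode durations, overall, by change
#' direction (step up vs step down), and by step, over uncensored episodes
#' only; the percentage of censored episodes is reported per stratum. A
#' stratum with no uncensored episode gets an absent (NA) summary, not zero.
#'
#' @param episodes episode table from [build_episode_table()].
#' @return list of tibbles `overall`, `by_direction`, `by_step`, each with
#'   `n`, `median_days`, `iqr_low`, `iqr_high`, `pct_censored`.
#' @export
summarise_durations <- function(episodes) {
  unc <- episodes[episodes$direction != "CENSORED", ]
  pct_cens <- function(sub) {
    if (nrow(sub) == 0) NA_real_ else 100 * mean(sub$direction == "CENSORED")
  }
  overall <- summarise_one(unc$duration_days)
  overall$pct_censored <- pct_cens(episodes)

  by_direction <- dplyr::bind_rows(lapply(c("UP", "DOWN"), function(d) {
    out <- summarise_one(unc$duration_days[unc$direction == d])
    out$direction <- d
    out
  }))[, c("direction", "n", "median_days", "iqr_low", "iqr_high")]

  by_step <- dplyr::bind_rows(c(
    list(tibble::tibble(step = integer(0), n = integer(0),
                        median_days = numeric(0), iqr_low = numeric(0),
                        iqr_high = numeric(0), pct_censored = numeric(0))),
    lapply(sort(unique(episodes$step)), function(s) {
    sub <- episodes[episodes$step == s, ]
      out <- summarise_one(sub$duration_days[sub$direction != "CENSORED"])
      out$step <- s
      out$pct_censored <- pct_cens(sub)
      out
    })))[, c("step", "n", "median_days", "iqr_low", "iqr_high", "pct_censored")]

  list(overall = overall, by_direction = by_direction, by_step = by_step)
}

#' Step transition counts and single-step-move fractions
#'
#' Counts transitions (step before, step after) over observed step changes;
#' the diagonal holds within-step regimen change counts. Transitions to and
#' from Step 0 can be excluded, as they often reflect periods of
#' non-adherence rather than sanctioned regimen changes.
#'
#' @param episodes episode table.
#' @param exclude_step0 drop transitions touching step 0 (and step-0
#'   within-step changes).
#' @return list with `matrix` (5x5 or 4x4 count matrix),
#'   `single_step_fraction_up`, `single_step_fraction_down` (percent of step
#'   ups / downs that moved exactly one step), and `long` (tibble
#'   `from`, `to`, `n` of off-diagonal transitions, Sankey-ready).
#' @export
transition_matrix <- function(episodes, exclude_step0 = FALSE) {
  steps_used <- if (exclude_step0) 1:4 else 0:4
  trans <- episodes[episodes$direction != "CENSORED", c("step", "next_step")]
  if (exclude_step0) {
    trans <- trans[trans$step != 0 & trans$next_step != 0, ]
  }
  m <- matrix(0L, length(steps_used), length(steps_used),
              dimnames = list(from = steps_used, to = steps_used))
  if (nrow(trans) > 0) {
    tab <- table(factor(trans$step, steps_used), factor(trans$next_step, steps_used))
    m <- m + unclass(tab)
  }
  keep <- episodes$step %in% steps_used
  diag(m) <- vapply(steps_used, function(s) {
    sum(episodes$regimen_changes_within[keep & episodes$step == s])
  }, numeric(1))
  delta <- trans$next_step - trans$step
  frac <- function(d) {
    moves <- delta[sign(delta) == d]
    if (length(moves) == 0) NA_real_ else 100 * mean(abs(moves) == 1)
  }
  long <- tibble::as_tibble(as.data.frame(as.table(m), stringsAsFactors = FALSE))
  names(long) <- c("from", "to", "n")
  long <- long[long$from != long$to & long$n > 0, ]
  list(matrix = m,
       single_step_fraction_up = frac(1),
       single_step_fraction_down = frac(-1),
       long = long)
}

#' Per person-year step mixing summary
#'
#' Person-years are 365-day blocks anchored at each patient's first event;
#' blocks with no prescription event are excluded from the denominator. For
#' each person-year with at least one event, counts the distinct steps
#' occupied and the number of step changes between consecutive events inside
#' the block.
#'
#' @param events event table.
#' @return list with `per_year` (tibble `patient_id`, `year_index`,
#'   `n_events`, `distinct_steps`, `n_changes`) and `aggregate` (tibble with
#'   `person_years`, `pct_single_step`, `pct_two_steps`,
#'   `pct_three_plus_steps`, `pct_three_plus_changes`).
#' @export
person_year_summary <- function(events) {
  per <- lapply(split(events, events$patient_id), function(ev) {
    ev <- ev[order(as.Date(ev$event_date)), ]
    d <- as.Date(ev$event_date)
    yr <- as.integer(floor(as.numeric(d - d[1]) / 365)) + 1L
    dplyr::bind_rows(lapply(unique(yr), function(y) {
      s <- ev$step[yr == y]
      tibble::tibble(patient_id = ev$patient_id[1], year_index = y,
                     n_events = length(s),
                     distinct_steps = length(unique(s)),
                     n_changes = if (length(s) < 2) 0L else sum(s[-1] != s[-length(s)]))
    }))
  })
  per <- dplyr::bind_rows(per)
  agg <- tibble::tibble(
    person_years = nrow(per),
    pct_single_step = 100 * mean(per$distinct_steps == 1),
    pct_two_steps = 100 * mean(per$distinct_steps == 2),
    pct_three_plus_steps = 100 * mean(per$distinct_steps >= 3),
    pct_three_plus_changes = 100 * mean(per$n_changes >= 3)
  )
  list(per_year = per, aggregate = agg)
}
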