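#' @name triage-levels
#' @title Ordered triage categories and alert levels
#' @description The obstetric chart classifies an observation into ordered
#'   categories `none < green < yellow < red`; the general adult chart into
#'   alert levels `none < inform < emergency`. A total score of 0 sits below
#'   the green range (which starts at 1) and forms its own stratum.
NULL

MEOWS_CATEGORIES <- c("none", "green", "yellow", "red")
EWS_LEVELS <- c("none", "inform", "emergency")

meows_category <- function(x) factor(x, MEOWS_CATEGORIES, ordered = TRUE)
ews_level <- function(x) factor(x, EWS_LEVELS, ordered = TRUE)

#' Obstetric triage category of an observation score
#'
#' Maps a MEOWS observation score to its escalation category: `red` for a
#' total of 7 or more; `yellow` for a total of 5--6 or any single parameter
#' scoring 3; `green` for totals 1--4; `none` for a total of 0.
#'
#' @param score An `observation_score` from the MEOWS system, or an integer
#'   vector of totals (then `max_single` must be given too).
#' @param max_single Integer vector of largest single-parameter scores,
#'   required when `score` is given as plain totals.
#' @return An ordered factor with levels `none < green < yellow < red`.
#' @examples
#' meows_triage(3, max_single = 3)  # yellow via the single-3 rule
#' @export
meows_triage <- function(score, max_single = NULL) {
  if (inherits(score, "observation_score")) {
    total <- score$total; max_single <- score$max_single
  } else {
    total <- as.integer(score)
    if (is.null(max_single))
      stop("max_single is required when passing raw totals")
    max_single <- as.integer(max_single)
  }
  out <- rep("none", length(total))
  out[total >= 1] <- "green"
  out[(total >= 5 & total <= 6) | max_single == 3] <- "yellow"
  out[total >= 7] <- "red"
  meows_category(out)
}

#' General EWS alert level of an observation score
#'
#' `inform` (notify a physician) for a total of 2 or more; `emergency`
#' (call the emergency team) when the total exceeds 3.
#'
#' @param score An `observation_score` from the EWS system, or an integer
#'   vector of totals.
#' @return An ordered factor with levels `none < inform < emergency`.
#' @export
ews_alert <- function(score) {
  total <- if (inherits(score, "observation_score")) score$total
           else as.integer(score)
  out <- rep("none", length(total))
  out[total >= 2] <- "inform"
  out[total >= 4] <- "emergency"
  ews_level(out)
}

#' Aggregate a cohort of stays to one assessment per woman
#'
#' Scores every observation under both charts and reduces each woman's stay
#' to its worst moment: the highest obstetric triage category, highest
#' general-EWS alert level, and maximum totals reached at any observation.
#' The worst observation over the stay is the screening-relevant summary: a
#' warning chart triggers on any single crossing.
#'
#' @param data Long-format cohort table (see [cohort_schema()]): one row per
#'   observation with `woman_id`, `timestamp`, vital-sign columns and a
#'   per-woman `morbidity` label. An optional logical `red_override` column
#'   forces the obstetric category to `red` for that woman (the chart's
#'   clinical-deterioration override, which is not computable from vitals).
#' @param meows,ews The two scoring systems; defaults rebuild the charts.
#' @return A `stay_assessment` data frame, one row per woman: `woman_id`,
#'   `worst_meows`, `max_meows_total`, `max_meows_single`, `worst_ews`,
#'   `max_ews_total`, `morbidity`.
#' @export
assess_cohort <- function(data, meows = build_meows_system(),
                          ews = build_ews_system()) {
  if (!nrow(data)) stop("cohort has no observations")
  stopifnot(all(c("woman_id", "morbidity") %in% names(data)))
  ms <- score_cohort(data, meows)
  es <- score_cohort(data, ews)
  cat_obs <- meows_triage(ms$total, ms$max_single)
  lev_obs <- ews_alert(es$total)

  id <- factor(data$woman_id, levels = unique(data$woman_id))
  worst_meows <- meows_category(
    MEOWS_CATEGORIES[tapply(as.integer(cat_obs), id, max)])
  worst_ews <- ews_level(EWS_LEVELS[tapply(as.integer(lev_obs), id, max)])
  morb <- tapply(data$morbidity, id, function(m) {
    u <- unique(m)
    if (length(u) != 1) stop("conflicting morbidity labels within a stay")
    as.logical(u)
  })
  out <- data.frame(
    woman_id = levels(id),
    worst_meows = worst_meows,
    max_meows_total = as.integer(tapply(ms$total, id, max)),
    max_meows_single = as.integer(tapply(ms$max_single, id, max)),
    worst_ews = worst_ews,
    max_ews_total = as.integer(tapply(es$total, id, max)),
    morbidity = as.logical(morb),
    row.names = NULL)
  if ("red_override" %in% names(data)) {
    forced <- as.logical(tapply(data$red_override, id, any))
    out$worst_meows[forced %in% TRUE] <- "red"
  }
  class(out) <- c("stay_assessment", "data.frame")
  out
}

#' Aggregate a single stay
#'
#' Convenience wrapper around [assess_cohort()] for one woman's
#' observations.
#'
#' @param stay Data frame of one woman's observations (all rows must share
#'   one `woman_id` and one `morbidity` value).
#' @inheritParams assess_cohort
#' @return A one-row `stay_assessment`.
#' @export
aggregate_stay <- function(stay, meows = build_meows_system(),
                           ews = build_ews_system()) {
  if (!nrow(stay)) stop("stay has no observations")
  if (length(unique(stay$woman_id)) != 1)
    stop("aggregate_stay expects observations from a single woman")
  assess_cohort(stay, meows, ews)
}

#' Binary test definitions evaluated against the morbidity label
#'
#' The six screening definitions compared in the study: obstetric chart
#' `red or yellow` (escalation threshold), `red` only, the exclusive
#' `yellow` and `green` strata, and the general chart's `inform`
#' (total >= 2) and `emergency` (total >= 4) thresholds.
#'
#' @return Named character vector of definition ids and labels.
#' @export
test_definitions <- function() {
  c(meows_red_or_yellow = "MEOWS red or yellow",
    meows_red = "MEOWS red",
    meows_yellow = "MEOWS yellow",
    meows_green = "MEOWS green",
    ews_inform = "EWS >= 2 points",
    ews_emergency = "EWS >= 4 points")
}

#' Apply a test definition to stay assessments
#'
#' Threshold definitions (`meows_red_or_yellow`, `meows_red`, `ews_inform`,
#' `ews_emergency`) compare the worst category by order; the exclusive
#' stratum definitions (`meows_yellow`, `meows_green`) require equality, so
#' a `red` woman is negative under `meows_yellow` and a score-0 (`none`)
#' woman is negative under `meows_green`.
#'
#' @param assessment A `stay_assessment` data frame (or one row of it).
#' @param definition One of `names(test_definitions())`.
#' @return Logical vector, one per woman.
#' @export
test_positive <- function(assessment, definition) {
  wm <- assessment$worst_meows
  we <- assessment$worst_ews
  switch(definition,
    meows_red_or_yellow = wm >= "yellow",
    meows_red = wm == "red",
    meows_yellow = wm == "yellow",
    meows_green = wm == "green",
    ews_inform = we >= "inform",
    ews_emergency = we == "emergency",
    stop("unknown test definition: ", definition))
}

#' @export
print.stay_assessment <- function(x, ...) {
  cat(sprintf("<stay_assessment> %d women, %d with severe morbidity\n",
              nrow(x), sum(x$morbidity)))
  print(table(meows = x$worst_meows, ews = x$worst_ews))
  invisible(x)
}

#' @export
summary.stay_assessment <- function(object, ...) {
  cat(sprintf("Stays: %d   severe morbidity: %d (%.1f%%)\n", nrow(object),
              sum(object$morbidity), 100 * mean(object$morbidity)))
  cat("\nWorst obstetric (MEOWS) category by outcome:\n")
  print(table(object$worst_meows, morbid = object$morbidity))
  cat("\nWorst general (EWS) alert level by outcome:\n")
  print(table(object$worst_ews, morbid = object$morbidity))
  invisible(object)
}
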