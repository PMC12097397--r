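# Vectorised band matching. `values` may contain NA (missing -> no match).
band_match <- function(values, band, type) {
  if (type == "numeric") {
    lo_ok <- if (band$lo_closed) values >= band$lo else values > band$lo
    hi_ok <- if (band$hi_closed) values <= band$hi else values < band$hi
    ok <- lo_ok & hi_ok
  } else if (type == "logical") {
    ok <- values %in% TRUE
  } else {  # avpu
    ok <- values %in% band$levels
  }
  ok & !is.na(ok)
}

#' Score one parameter value against a chart rule
#'
#' Looks the value up in the rule's bands and returns the points awarded:
#' the maximum over all matching bands (overlapping printed bands, such as a
#' systolic pressure of exactly 150 on the obstetric chart, resolve upward
#' -- the safety-first reading), or 0 when no band matches. Missing values
#' score 0.
#'
#' @param value A parameter value (numeric, logical, or an AVPU letter);
#'   vectorised.
#' @param rule A single rule from a [build_meows_system()] /
#'   [build_ews_system()] object, e.g. `system$rules$sbp`.
#' @return Integer points, 0--3, one per value.
#' @examples
#' meows <- build_meows_system()
#' score_parameter(c(125, 55, 80), meows$rules$heart_rate)
#' @export
score_parameter <- function(value, rule) {
  if (rule$type == "numeric") {
    value <- as.numeric(value)
    # NaN is "invalid", not "missing": is.na(NaN) is TRUE, so test it first
    bad <- is.nan(value) | (!is.na(value) & !is.finite(value))
    if (any(bad))
      stop("non-finite value for parameter '", rule$parameter, "'")
  } else if (rule$type == "avpu") {
    value <- as.character(value)
    bad <- !is.na(value) & !(value %in% AVPU_LEVELS)
    if (any(bad))
      stop("invalid AVPU level: ", paste(unique(value[bad]), collapse = ", "))
  }
  pts <- integer(length(value))
  for (band in rule$bands) {
    hit <- band_match(value, band, rule$type)
    pts <- pmax(pts, band$points * hit)
  }
  as.integer(pts)
}

#' Score a cohort of observations under one system
#'
#' Vectorised scorer: takes a long-format table of observations (one row per
#' timestamped measurement set, columns named as in [cohort_schema()]) and
#' returns per-parameter points, the total, the largest single-parameter
#' score, and the number of missing parameters for every row. Parameters
#' with no column present are treated as missing throughout.
#'
#' @param data Data frame of observations.
#' @param system A `scoring_system`.
#' @return A data frame with one `pts_<parameter>` column per rule plus
#'   `total`, `max_single` and `n_missing`.
#' @export
score_cohort <- function(data, system) {
  n <- nrow(data)
  pts <- matrix(0L, n, length(system$rules),
                dimnames = list(NULL, names(system$rules)))
  miss <- integer(n)
  for (rule in system$rules) {
    p <- rule$parameter
    if (p %in% names(data)) {
      pts[, p] <- score_parameter(data[[p]], rule)
      miss <- miss + is.na(data[[p]])
    } else {
      miss <- miss + 1L
    }
  }
  out <- as.data.frame(pts)
  names(out) <- paste0("pts_", colnames(pts))
  out$total <- as.integer(rowSums(pts))
  out$max_single <- as.integer(apply(pts, 1, max))
  if (n == 0) out$max_single <- integer(0)
  out$n_missing <- miss
  out
}

#' Score a single observation
#'
#' @param obs A named list or one-row data frame with (a subset of) the nine
#'   vital-sign fields; missing parameters score 0 and are counted.
#' @param system A `scoring_system`.
#' @return An `observation_score`: list with `per_parameter` (named integer
#'   vector), `total`, `max_single`, `n_missing` and `system`.
#' @examples
#' meows <- build_meows_system()
#' score_observation(list(resp_rate = 23, spo2 = 93, o2_supplement = TRUE,
#'                        temperature = 37.5, sbp = 145, dbp = 95,
#'                        heart_rate = 115, avpu = "A", vas_pain = 5), meows)
#' @export
score_observation <- function(obs, system) {
  obs <- as.data.frame(lapply(obs, function(x) if (length(x)) x else NA),
                       stringsAsFactors = FALSE)
  sc <- score_cohort(obs, system)
  if (sc$n_missing == length(system$rules))
    stop("empty observation: all ", length(system$rules),
         " parameters missing under ", system$name)
  per <- unlist(sc[1, paste0("pts_", names(system$rules))])
  names(per) <- names(system$rules)
  structure(list(per_parameter = per, total = sc$total[1],
                 max_single = sc$max_single[1], n_missing = sc$n_missing[1],
                 system = system$name),
            class = "observation_score")
}

#' @export
print.observation_score <- function(x, ...) {
  cat(sprintf("<observation_score> %s total %d (max single %d, %d missing)\n",
              x$system, x$total, x$max_single, x$n_missing))
  nz <- x$per_parameter[x$per_parameter > 0]
  if (length(nz))
    cat("  ", paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n")
  invisible(x)
}

#' Validate an observation against physiological ranges and chart gaps
#'
#' Checks type-level invariants (SpO2 in 0--100, VAS in 0--10, rates,
#' pressures and temperature strictly positive and finite, AVPU one of
#' A/V/P/U) and, when a system is supplied, reports values that fall in the
#' chart's documented inter-band gaps (see [band_gaps()]) -- these score 0
#' by the literal reading but deserve a second look.
#'
#' @param obs Named list or one-row data frame of vital-sign fields.
#' @param system Optional `scoring_system` whose gaps should be checked.
#' @return A data frame with columns `parameter`, `kind`
#'   (`"range"`/`"type"`/`"band_gap"`) and `message`; zero rows when clean.
#' @export
validate_observation <- function(obs, system = NULL) {
  issues <- list()
  add <- function(parameter, kind, message)
    issues[[length(issues) + 1]] <<- data.frame(
      parameter = parameter, kind = kind, message = message)

  num_ranges <- list(
    spo2 = c(0, 100), vas_pain = c(0, 10),
    resp_rate = c(0, Inf), temperature = c(0, Inf), sbp = c(0, Inf),
    dbp = c(0, Inf), heart_rate = c(0, Inf))
  for (p in names(num_ranges)) {
    v <- obs[[p]]
    if (is.null(v) || length(v) == 0) next
    if (is.na(v) && !is.nan(v)) next
    v <- suppressWarnings(as.numeric(v))
    if (is.na(v) || !is.finite(v)) {
      add(p, "type", sprintf("%s is not a finite number", p))
    } else {
      r <- num_ranges[[p]]
      strict_pos <- !p %in% c("spo2", "vas_pain")
      if (v < r[1] || v > r[2] || (strict_pos && v <= 0))
        add(p, "range", sprintf("%s = %g outside [%g, %g]%s", p, v, r[1], r[2],
                                if (strict_pos) " (must be > 0)" else ""))
    }
  }
  v <- obs[["avpu"]]
  if (!is.null(v) && length(v) && !is.na(v) && !(v %in% AVPU_LEVELS))
    add("avpu", "type", sprintf("avpu = '%s' not one of A/V/P/U", v))
  v <- obs[["o2_supplement"]]
  if (!is.null(v) && length(v) && !is.na(v) &&
      !is.logical(v) && !(v %in% c(0, 1)))
    add("o2_supplement", "type", "o2_supplement must be logical (or 0/1)")

  if (!is.null(system)) {
    gaps <- band_gaps(system)
    for (i in seq_len(nrow(gaps))) {
      g <- gaps[i, ]
      v <- obs[[g$parameter]]
      if (is.null(v) || length(v) == 0 || is.na(v)) next
      v <- suppressWarnings(as.numeric(v))
      if (!is.na(v) && is.finite(v) && in_gap(v, g))
        add(g$parameter, "band_gap",
            sprintf("%s = %g falls in an unscored gap of the %s chart",
                    g$parameter, v, system$name))
    }
  }
  if (!length(issues))
    return(data.frame(parameter = character(), kind = character(),
                      message = character()))
  do.call(rbind, issues)
}
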