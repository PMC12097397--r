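# The nine monitored parameters, in chart order. `avpu` is categorical
# (A/V/P/U), `o2_supplement` logical, the rest numeric.
VITAL_PARAMETERS <- c(
  "resp_rate", "spo2", "o2_supplement", "temperature",
  "sbp", "dbp", "heart_rate", "avpu", "vas_pain"
)

PARAMETER_TYPES <- c(
  resp_rate = "numeric", spo2 = "numeric", o2_supplement = "logical",
  temperature = "numeric", sbp = "numeric", dbp = "numeric",
  heart_rate = "numeric", avpu = "avpu", vas_pain = "numeric"
)

# Typical normal resting values, used only to tell a genuine inter-band gap
# from the chart's normal (zero-score) region when scanning band coverage.
REFERENCE_NORMALS <- c(
  resp_rate = 16, spo2 = 98, temperature = 37, sbp = 120, dbp = 75,
  heart_rate = 80, vas_pain = 0
)

AVPU_LEVELS <- c("A", "V", "P", "U")

band_num <- function(points, lo = -Inf, hi = Inf,
                     lo_closed = TRUE, hi_closed = TRUE) {
  stopifnot(points %in% 1:3, lo <= hi)
  list(points = as.integer(points), lo = lo, hi = hi,
       lo_closed = lo_closed, hi_closed = hi_closed)
}

band_flag <- function(points) {
  list(points = as.integer(points), flag = TRUE)
}

band_levels <- function(points, levels) {
  stopifnot(all(levels %in% AVPU_LEVELS))
  list(points = as.integer(points), levels = levels)
}

parameter_rule <- function(parameter, bands) {
  stopifnot(parameter %in% VITAL_PARAMETERS)
  structure(list(parameter = parameter,
                 type = unname(PARAMETER_TYPES[parameter]),
                 bands = bands),
            class = "parameter_rule")
}

new_scoring_system <- function(name, rules) {
  names(rules) <- vapply(rules, `[[`, "", "parameter")
  if (anyDuplicated(names(rules)) > 0)
    stop("a parameter may appear in at most one rule")
  structure(list(name = name, rules = rules), class = "scoring_system")
}

#' Obstetric early-warning (MEOWS) scoring system
#'
#' Builds the Modified Early Obstetric Warning System chart: nine parameter
#' rules (respiratory rate, SpO2, oxygen supplementation, temperature,
#' systolic and diastolic blood pressure, heart rate, AVPU consciousness
#' level, VAS pain), each mapping value bands to 1--3 points. Values outside
#' every band score 0. Printed interval bounds are closed (`21--25` means
#' \eqn{[21, 25]}); `<` and `>` are strict. A value falling in two
#' overlapping bands (e.g. a systolic pressure of exactly 150) takes the
#' higher score.
#'
#' @return A `scoring_system` object with nine rules.
#' @seealso [build_ews_system()], [score_observation()]
#' @examples
#' meows <- build_meows_system()
#' score_parameter(165, meows$rules$sbp)  # 3 points
#' @export
build_meows_system <- function() {
  new_scoring_system("MEOWS", list(
    parameter_rule("resp_rate", list(
      band_num(2, 21, 25),
      band_num(3, hi = 12, hi_closed = FALSE),
      band_num(3, lo = 25, lo_closed = FALSE))),
    parameter_rule("spo2", list(
      band_num(2, 92, 95),
      band_num(3, hi = 92, hi_closed = FALSE))),
    parameter_rule("o2_supplement", list(band_flag(2))),
    parameter_rule("temperature", list(
      band_num(2, 37.3, 37.7),
      band_num(3, lo = 37.7, lo_closed = FALSE),
      band_num(3, hi = 36.0, hi_closed = FALSE))),
    parameter_rule("sbp", list(
      band_num(1, 140, 150),
      band_num(2, 150, 160),
      band_num(3, lo = 160, lo_closed = FALSE),
      band_num(3, hi = 90, hi_closed = FALSE))),
    parameter_rule("dbp", list(
      band_num(1, 90, 100),
      band_num(2, 100, 110),
      band_num(3, lo = 110, lo_closed = FALSE))),
    parameter_rule("heart_rate", list(
      band_num(1, 110, 120),
      band_num(2, 120, 130),
      band_num(2, 50, 60),
      band_num(3, lo = 130, lo_closed = FALSE),
      band_num(3, hi = 50, hi_closed = FALSE))),
    parameter_rule("avpu", list(band_levels(3, c("V", "P", "U")))),
    parameter_rule("vas_pain", list(
      band_num(2, 4, 7),
      band_num(3, lo = 7)))
  ))
}

#' General adult early-warning (EWS) scoring system
#'
#' Builds the non-obstetric adult early warning chart used for the
#' comparison arm: five rules (heart rate, systolic blood pressure,
#' respiratory rate, temperature, AVPU). The chart is encoded literally,
#' including its printed gaps: a heart rate of exactly 40 or 130, a
#' respiratory rate of exactly 30, and a systolic pressure of exactly 70
#' fall between bands and score 0 (flagged by [validate_observation()]).
#' The temperature row has no 3-point band.
#'
#' @return A `scoring_system` object with five rules.
#' @seealso [build_meows_system()]
#' @export
build_ews_system <- function() {
  new_scoring_system("EWS", list(
    parameter_rule("heart_rate", list(
      band_num(1, 41, 50),
      band_num(1, 101, 110),
      band_num(2, 111, 129),
      band_num(2, hi = 40, hi_closed = FALSE),
      band_num(3, lo = 130, lo_closed = FALSE))),
    parameter_rule("sbp", list(
      band_num(1, 81, 100),
      band_num(2, 71, 80),
      band_num(2, lo = 200, lo_closed = FALSE),
      band_num(3, hi = 70, hi_closed = FALSE))),
    parameter_rule("resp_rate", list(
      band_num(1, 15, 20),
      band_num(2, 21, 29),
      band_num(2, hi = 8, hi_closed = FALSE),
      band_num(3, lo = 30, lo_closed = FALSE))),
    parameter_rule("temperature", list(
      band_num(1, 35.1, 36.5),
      band_num(1, lo = 37.5, lo_closed = FALSE),
      band_num(2, hi = 35, hi_closed = FALSE))),
    parameter_rule("avpu", list(
      band_levels(1, "V"),
      band_levels(2, "P"),
      band_levels(3, "U")))
  ))
}

#' @export
print.scoring_system <- function(x, ...) {
  cat(sprintf("<scoring_system> %s (%d parameter rules)\n",
              x$name, length(x$rules)))
  for (rule in x$rules) {
    cat(sprintf("  %-14s %s\n", rule$parameter,
                paste(vapply(rule$bands, describe_band, ""), collapse = "; ")))
  }
  invisible(x)
}

describe_band <- function(b) {
  txt <- if (!is.null(b$flag)) {
    "yes"
  } else if (!is.null(b$levels)) {
    paste(b$levels, collapse = "/")
  } else if (is.finite(b$lo) && is.finite(b$hi)) {
    sprintf("%g-%g", b$lo, b$hi)
  } else if (is.finite(b$lo)) {
    sprintf("%s%g", if (b$lo_closed) ">=" else ">", b$lo)
  } else {
    sprintf("%s%g", if (b$hi_closed) "<=" else "<", b$hi)
  }
  sprintf("%s→%d", txt, b$points)
}

#' Inter-band gaps of a scoring system
#'
#' Scans each numeric rule's band coverage and reports narrow zero-score
#' intervals squeezed between two scoring bands -- places where the printed
#' chart leaves a value unscored (e.g. the general EWS chart scores a heart
#' rate of 39 and of 41 but not of exactly 40). A zero-score interval is
#' reported as a gap when it is bounded by scoring bands on both sides, is
#' at most one unit wide, and does not contain the parameter's typical
#' normal value (so the chart's deliberate normal region is not reported).
#'
#' @param system A `scoring_system`.
#' @return A data frame with columns `parameter`, `lo`, `hi`, `lo_open`,
#'   `hi_open` describing each gap interval.
#' @export
band_gaps <- function(system) {
  out <- list()
  for (rule in system$rules) {
    if (rule$type != "numeric") next
    ivs <- lapply(rule$bands, function(b)
      c(lo = b$lo, hi = b$hi, lo_closed = b$lo_closed, hi_closed = b$hi_closed))
    ivs <- ivs[order(vapply(ivs, `[[`, 0, "lo"))]
    for (i in seq_len(length(ivs) - 1)) {
      a <- ivs[[i]]; b <- ivs[[i + 1]]
      if (b[["lo"]] < a[["hi"]] ||
          (b[["lo"]] == a[["hi"]] && (a[["hi_closed"]] || b[["lo_closed"]])))
        next  # adjacent or overlapping: no gap
      width <- b[["lo"]] - a[["hi"]]
      if (width > 1) next
      normal <- REFERENCE_NORMALS[[rule$parameter]]
      gap_lo <- a[["hi"]]; gap_hi <- b[["lo"]]
      in_gap <- (normal > gap_lo || (a[["hi_closed"]] == 0 && normal == gap_lo)) &&
        (normal < gap_hi || (b[["lo_closed"]] == 0 && normal == gap_hi))
      if (in_gap) next
      out[[length(out) + 1]] <- data.frame(
        parameter = rule$parameter, lo = gap_lo, hi = gap_hi,
        lo_open = as.logical(a[["hi_closed"]]),
        hi_open = as.logical(b[["lo_closed"]]))
    }
  }
  if (!length(out))
    return(data.frame(parameter = character(), lo = numeric(), hi = numeric(),
                      lo_open = logical(), hi_open = logical()))
  do.call(rbind, out)
}

in_gap <- function(value, gap) {
  above <- if (gap$lo_open) value > gap$lo else value >= gap$lo
  below <- if (gap$hi_open) value < gap$hi else value <= gap$hi
  above & below
}

#' Write a scoring system to a YAML configuration file
#'
#' The scoring engine is data-driven: the built-in charts serialize to a
#' plain YAML document (one entry per band) and read back bit-exactly, so a
#' site can audit or swap the chart without touching code.
#'
#' @param system A `scoring_system`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_scoring_system <- function(system, path) {
  doc <- list(name = system$name, rules = lapply(unname(system$rules), function(r) {
    list(parameter = r$parameter, type = r$type,
         bands = lapply(r$bands, function(b) {
           b$points <- as.integer(b$points)
           b
         }))
  }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a scoring system from a YAML configuration file
#'
#' @param path File written by [write_scoring_system()] (or hand-authored in
#'   the same schema).
#' @return A `scoring_system`.
#' @export
read_scoring_system <- function(path) {
  doc <- yaml::read_yaml(path)
  rules <- lapply(doc$rules, function(r) {
    bands <- lapply(r$bands, function(b) {
      b$points <- as.integer(b$points)
      if (!is.null(b$lo)) {
        b$lo <- as.numeric(b$lo); b$hi <- as.numeric(b$hi)
      }
      if (!is.null(b$levels)) b$levels <- as.character(b$levels)
      b
    })
    parameter_rule(r$parameter, bands)
  })
  new_scoring_system(doc$name, rules)
}
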