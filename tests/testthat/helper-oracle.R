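# Brute-force scoring oracle: evaluates every band of a rule independently
# with scalar logic and takes the maximum. Kept deliberately separate from
# the package's vectorised band matcher.
oracle_score_one <- function(value, rule) {
  if (is.na(value)) return(0L)
  best <- 0L
  for (b in rule$bands) {
    hit <- if (!is.null(b$flag)) {
      isTRUE(as.logical(value))
    } else if (!is.null(b$levels)) {
      value %in% b$levels
    } else {
      lo_ok <- if (b$lo_closed) value >= b$lo else value > b$lo
      hi_ok <- if (b$hi_closed) value <= b$hi else value < b$hi
      lo_ok && hi_ok
    }
    if (hit) best <- max(best, b$points)
  }
  as.integer(best)
}

oracle_score <- function(values, rule) {
  vapply(values, oracle_score_one, integer(1), rule = rule,
         USE.NAMES = FALSE)
}

# A complete normal observation (scores 0 on both charts).
normal_obs <- function(...) {
  obs <- list(resp_rate = 16, spo2 = 98, o2_supplement = FALSE,
              temperature = 36.8, sbp = 120, dbp = 75, heart_rate = 80,
              avpu = "A", vas_pain = 2)
  utils::modifyList(obs, list(...))
}

# The published accuracy table, cell by cell (point and 95% CI as printed).
published_table <- list(
  meows_red_or_yellow = c(
    sensitivity = "92% (73%-99%)", specificity = "62% (58%-66%)",
    ppv = "8% (7%-9%)", npv = "100% (98%-100%)",
    plr = "2.4 (2.1-2.8)", nlr = "0.1 (0.04-0.5)"),
  meows_red = c(
    sensitivity = "58% (37%-78%)", specificity = "99% (98%-100%)",
    ppv = "70% (50%-85%)", npv = "99% (98%-99%)",
    plr = "68.0 (28.6-161.5)", nlr = "0.4 (0.3-0.7)"),
  meows_yellow = c(
    sensitivity = "33% (16%-55%)", specificity = "63% (59%-67%)",
    ppv = "3% (2%-5%)", npv = "96% (95%-97%)",
    plr = "0.9 (0.5-1.6)", nlr = "1.1 (0.8-1.4)"),
  meows_green = c(
    sensitivity = "8% (1%-27%)", specificity = "58% (54%-62%)",
    ppv = "0.7% (0.2%-2.5%)", npv = "95% (94%-95%)",
    plr = "0.2 (0.1-0.8)", nlr = "1.6 (1.4-1.8)"),
  ews_inform = c(
    sensitivity = "63% (41%-81%)", specificity = "66% (62%-69%)",
    ppv = "6% (4%-8%)", npv = "98% (97%-99%)",
    plr = "1.8 (1.3-2.5)", nlr = "0.6 (0.3-1.0)"),
  ews_emergency = c(
    sensitivity = "8% (1%-27%)", specificity = "99% (98%-100%)",
    ppv = "25% (7%-61%)", npv = "97% (97%-97%)",
    plr = "9.7 (2.1-45.6)", nlr = "0.9 (0.8-1.0)"))

point_of <- function(cell) sub(" \\(.*", "", cell)

# Build a stay_assessment table directly from worst categories -- used to
# test the diagnostics layer without going through the scorer.
make_assessments <- function(worst_meows, morbidity,
                             worst_ews = rep("none", length(worst_meows))) {
  out <- data.frame(
    woman_id = sprintf("W%04d", seq_along(worst_meows)),
    worst_meows = factor(worst_meows, c("none", "green", "yellow", "red"),
                         ordered = TRUE),
    max_meows_total = 0L, max_meows_single = 0L,
    worst_ews = factor(worst_ews, c("none", "inform", "emergency"),
                       ordered = TRUE),
    max_ews_total = 0L,
    morbidity = morbidity)
  class(out) <- c("stay_assessment", "data.frame")
  out
}
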