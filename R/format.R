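# Half-up decimal rounding (round() is banker's rounding; published tables
# use conventional half-up).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Proportions print as integer percent, except values below 1% keep one
# decimal (so a PPV of 2/296 prints "0.7%", not "1%").
fmt_percent <- function(p) {
  ifelse(is.na(p), "-",
         ifelse(p < 0.01 & p > 0,
                sprintf("%.1f%%", round_half_up(100 * p, 1)),
                sprintf("%.0f%%", round_half_up(100 * p, 0))))
}

# Prevalence-style percent: always one decimal ("3.3%").
fmt_percent_1dp <- function(p) sprintf("%.1f%%", round_half_up(100 * p, 1))

# Ratios print to one decimal, except values below 0.05 to two decimals
# (an NLR lower bound of 0.036 prints "0.04", not "0.0").
fmt_ratio <- function(r) {
  ifelse(is.na(r), "-",
         ifelse(is.infinite(r), "Inf",
                ifelse(abs(r) < 0.05,
                       sprintf("%.2f", round_half_up(r, 2)),
                       sprintf("%.1f", round_half_up(r, 1)))))
}

# A proportion cell (point + CI) switches to one decimal as a whole when the
# point estimate is below 1%, so "0.7% (0.2%-2.5%)" keeps consistent
# precision across its bounds.
fmt_prop_ci <- function(e) {
  if (!is.na(e$point) && e$point < 0.01 && e$point > 0) {
    f <- function(p) ifelse(is.na(p), "-", fmt_percent_1dp(p))
    sprintf("%s (%s-%s)", f(e$point), f(e$lo), f(e$hi))
  } else {
    sprintf("%s (%s-%s)", fmt_percent(e$point), fmt_percent(e$lo),
            fmt_percent(e$hi))
  }
}

fmt_ratio_ci <- function(e) {
  sprintf("%s (%s-%s)", fmt_ratio(e$point), fmt_ratio(e$lo),
          fmt_ratio(e$hi))
}

#' Format a diagnostic report the way the published table prints it
#'
#' Presentation-only rounding, applied after all computation: proportions as
#' integer percent (one decimal below 1%), likelihood ratios to one decimal
#' (two decimals below 0.05), all half-up.
#'
#' @param report A `diagnostic_report`.
#' @return Named character vector: `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `plr`, `nlr`, each as `"point (lo-hi)"`.
#' @examples
#' format_report(diagnostic_report(new_confusion_matrix(14, 6, 10, 693)))
#' @export
format_report <- function(report) {
  c(sensitivity = fmt_prop_ci(report$sensitivity),
    specificity = fmt_prop_ci(report$specificity),
    ppv = fmt_prop_ci(report$ppv),
    npv = fmt_prop_ci(report$npv),
    plr = fmt_ratio_ci(report$plr),
    nlr = fmt_ratio_ci(report$nlr))
}
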