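#' Build a 2x2 confusion matrix for one test definition
#'
#' @param assessments A `stay_assessment` data frame.
#' @param definition One of `names(test_definitions())`.
#' @return A `confusion_matrix`: named integer vector `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_matrix <- function(assessments, definition) {
  if (!nrow(assessments)) stop("no assessments")
  pos <- test_positive(assessments, definition)
  d <- assessments$morbidity
  new_confusion_matrix(sum(pos & d), sum(pos & !d), sum(!pos & d),
                       sum(!pos & !d))
}

#' @rdname confusion_matrix
#' @param tp,fp,fn,tn Cell counts (true/false positives/negatives).
#' @export
new_confusion_matrix <- function(tp, fp, fn, tn) {
  m <- as.integer(c(tp = tp, fp = fp, fn = fn, tn = tn))
  names(m) <- c("tp", "fp", "fn", "tn")
  if (any(m < 0)) stop("confusion-matrix cells must be non-negative")
  structure(m, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(x[c("tp", "fp", "fn", "tn")], 2, 2, byrow = TRUE,
              dimnames = list(test = c("positive", "negative"),
                              morbidity = c("yes", "no")))
  print(m)
  invisible(x)
}

estimate_ci <- function(point, lo, hi, level, method, degenerate = FALSE) {
  structure(list(point = point, lo = lo, hi = hi, level = level,
                 method = method, degenerate = degenerate),
            class = "estimate_ci")
}

#' @export
print.estimate_ci <- function(x, ...) {
  cat(sprintf("%.4g (%g%% CI %.4g-%.4g)%s [%s]\n", x$point, 100 * x$level,
              x$lo, x$hi, if (x$degenerate) " [degenerate]" else "",
              x$method))
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Exact two-sided interval for a binomial proportion from beta quantiles:
#' lower bound `qbeta(a/2, x, n-x+1)` (0 when `x = 0`), upper bound
#' `qbeta(1-a/2, x+1, n-x)` (1 when `x = n`).
#'
#' @param x Number of successes.
#' @param n Number of trials (>= 1).
#' @param level Confidence level, default 0.95.
#' @return An `estimate_ci` with `point = x/n`.
#' @examples
#' clopper_pearson(14, 24)  # 58% (37%-78%)
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  if (n < 1) stop("undefined estimate: n must be >= 1")
  if (x < 0 || x > n) stop("x must be in 0..n")
  a <- (1 - level) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  estimate_ci(x / n, lo, hi, level, "clopper-pearson")
}

#' Sensitivity and specificity with exact intervals
#'
#' @param m A `confusion_matrix`.
#' @param level Confidence level.
#' @return List with elements `sensitivity` and `specificity`, each an
#'   `estimate_ci` (Clopper-Pearson).
#' @export
sens_spec <- function(m, level = 0.95) {
  n1 <- m[["tp"]] + m[["fn"]]
  n0 <- m[["fp"]] + m[["tn"]]
  if (n1 < 1 || n0 < 1)
    stop("undefined estimate: need at least one diseased and one ",
         "non-diseased subject")
  se <- clopper_pearson(m[["tp"]], n1, level)
  sp <- clopper_pearson(m[["tn"]], n0, level)
  se$method <- sp$method <- "clopper-pearson"
  list(sensitivity = se, specificity = sp)
}

#' Predictive values with standard-logit intervals
#'
#' PPV = tp/(tp+fp), NPV = tn/(tn+fn) at the sample prevalence. Intervals
#' use the standard logit method, whose variance combines sensitivity,
#' specificity and the group sizes:
#' \deqn{var(logit PPV) = (1-se)/(se\,n_1) + sp/((1-sp)\,n_0)}
#' \deqn{var(logit NPV) = se/((1-se)\,n_1) + (1-sp)/(sp\,n_0)}
#' with \eqn{n_1 = tp+fn}, \eqn{n_0 = fp+tn}. When sensitivity or
#' specificity is exactly 0 or 1 a variance term is infinite; the affected
#' bound collapses to 0 or 1 and the interval is flagged degenerate.
#'
#' @param m A `confusion_matrix`.
#' @param level Confidence level.
#' @return List with `estimate_ci` elements `ppv` and `npv`.
#' @export
predictive_values <- function(m, level = 0.95) {
  tp <- m[["tp"]]; fp <- m[["fp"]]; fn <- m[["fn"]]; tn <- m[["tn"]]
  if (tp + fp < 1) stop("undefined estimate: no test positives (ppv)")
  if (tn + fn < 1) stop("undefined estimate: no test negatives (npv)")
  n1 <- tp + fn; n0 <- fp + tn
  se <- tp / n1; sp <- tn / n0
  z <- stats::qnorm(1 - (1 - level) / 2)
  logit <- function(p) log(p / (1 - p))
  inv_logit <- function(x) 1 / (1 + exp(-x))

  logit_ci <- function(point, v) {
    if (!is.finite(v) || point %in% c(0, 1)) {
      return(estimate_ci(point, if (point == 1) NA_real_ else 0,
                         if (point == 0) NA_real_ else 1,
                         level, "standard-logit", degenerate = TRUE))
    }
    s <- sqrt(v)
    estimate_ci(point, inv_logit(logit(point) - z * s),
                inv_logit(logit(point) + z * s), level, "standard-logit")
  }
  v_ppv <- (1 - se) / (se * n1) + sp / ((1 - sp) * n0)
  v_npv <- se / ((1 - se) * n1) + (1 - sp) / (sp * n0)
  list(ppv = logit_ci(tp / (tp + fp), v_ppv),
       npv = logit_ci(tn / (tn + fn), v_npv))
}

#' Likelihood ratios with log-method intervals
#'
#' PLR = se/(1-sp), NLR = (1-se)/sp, with intervals on the log scale:
#' \deqn{SE(\ln PLR) = \sqrt{1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn)}}
#' \deqn{SE(\ln NLR) = \sqrt{1/fn - 1/(tp+fn) + 1/tn - 1/(fp+tn)}}
#' A zero cell makes a ratio infinite (fp = 0: PLR infinite) or zero
#' (fn = 0: NLR 0, lower bound 0 by convention); such intervals are flagged
#' degenerate rather than continuity-corrected.
#'
#' @param m A `confusion_matrix`.
#' @param level Confidence level.
#' @return List with `estimate_ci` elements `plr` and `nlr`.
#' @export
likelihood_ratios <- function(m, level = 0.95) {
  tp <- m[["tp"]]; fp <- m[["fp"]]; fn <- m[["fn"]]; tn <- m[["tn"]]
  n1 <- tp + fn; n0 <- fp + tn
  if (n1 < 1 || n0 < 1)
    stop("undefined estimate: need diseased and non-diseased subjects")
  se <- tp / n1; sp <- tn / n0
  z <- stats::qnorm(1 - (1 - level) / 2)

  plr <- if (sp < 1) se / (1 - sp) else Inf
  if (tp == 0 || fp == 0 || !is.finite(plr)) {
    plr_ci <- estimate_ci(plr, if (tp == 0) 0 else NA_real_,
                          if (fp == 0) Inf else NA_real_,
                          level, "log", degenerate = TRUE)
  } else {
    s <- sqrt(1 / tp - 1 / n1 + 1 / fp - 1 / n0)
    plr_ci <- estimate_ci(plr, exp(log(plr) - z * s), exp(log(plr) + z * s),
                          level, "log")
  }
  nlr <- if (sp > 0) (1 - se) / sp else Inf
  if (fn == 0 || tn == 0 || !is.finite(nlr)) {
    nlr_ci <- estimate_ci(nlr, if (fn == 0) 0 else NA_real_,
                          if (tn == 0) Inf else NA_real_,
                          level, "log", degenerate = TRUE)
  } else {
    s <- sqrt(1 / fn - 1 / n1 + 1 / tn - 1 / n0)
    nlr_ci <- estimate_ci(nlr, exp(log(nlr) - z * s), exp(log(nlr) + z * s),
                          level, "log")
  }
  list(plr = plr_ci, nlr = nlr_ci)
}

#' Full diagnostic-accuracy report for one 2x2 matrix
#'
#' @param m A `confusion_matrix`.
#' @param label Human-readable test label.
#' @param level Confidence level.
#' @return A `diagnostic_report`: the matrix, sample prevalence, and
#'   `estimate_ci` entries for sensitivity, specificity, PPV, NPV, PLR and
#'   NLR.
#' @export
diagnostic_report <- function(m, label = "", level = 0.95) {
  ss <- sens_spec(m, level)
  pv <- predictive_values(m, level)
  lr <- likelihood_ratios(m, level)
  n <- sum(m)
  structure(c(list(label = label, matrix = m, n = n,
                   prevalence = (m[["tp"]] + m[["fn"]]) / n),
              ss, pv, lr),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("<diagnostic_report> %s  (tp %d, fp %d, fn %d, tn %d)\n",
              x$label, x$matrix[["tp"]], x$matrix[["fp"]],
              x$matrix[["fn"]], x$matrix[["tn"]]))
  f <- format_report(x)
  for (s in names(f)) cat(sprintf("  %-12s %s\n", s, f[[s]]))
  invisible(x)
}

#' Evaluate a cohort against all six test definitions
#'
#' The estimator-style entry point: reduces stay assessments to the six
#' published screening definitions (obstetric red-or-yellow, red, exclusive
#' yellow, exclusive green; general chart inform and emergency thresholds)
#' and computes the full accuracy report for each, plus cohort prevalence.
#'
#' @param assessments A `stay_assessment` data frame (from
#'   [assess_cohort()]).
#' @param level Confidence level for all intervals.
#' @return A `dx_comparison`: list of six `diagnostic_report`s, prevalence
#'   (`estimate_ci`), and cohort size. Has `print`, `summary` and
#'   `as.data.frame` methods.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_women = 200), seed = 1)
#' ev <- evaluate_cohort(assess_cohort(cohort))
#' ev
#' @export
evaluate_cohort <- function(assessments, level = 0.95) {
  n_morbid <- sum(assessments$morbidity)
  n <- nrow(assessments)
  if (n_morbid == 0 || n_morbid == n)
    stop("degenerate cohort: sensitivity/specificity undefined (",
         n_morbid, " of ", n, " morbid)")
  defs <- test_definitions()
  reports <- lapply(names(defs), function(d)
    diagnostic_report(confusion_matrix(assessments, d), defs[[d]], level))
  names(reports) <- names(defs)
  structure(list(reports = reports,
                 prevalence = clopper_pearson(n_morbid, n, level),
                 n = n, n_morbid = n_morbid, level = level),
            class = "dx_comparison")
}

#' @export
as.data.frame.dx_comparison <- function(x, ..., formatted = FALSE) {
  rows <- lapply(x$reports, function(r) {
    if (formatted) {
      f <- format_report(r)
      data.frame(test = r$label, t(unclass(f)))
    } else {
      data.frame(
        test = r$label,
        tp = r$matrix[["tp"]], fp = r$matrix[["fp"]],
        fn = r$matrix[["fn"]], tn = r$matrix[["tn"]],
        sensitivity = r$sensitivity$point,
        sensitivity_lo = r$sensitivity$lo, sensitivity_hi = r$sensitivity$hi,
        specificity = r$specificity$point,
        specificity_lo = r$specificity$lo, specificity_hi = r$specificity$hi,
        ppv = r$ppv$point, ppv_lo = r$ppv$lo, ppv_hi = r$ppv$hi,
        npv = r$npv$point, npv_lo = r$npv$lo, npv_hi = r$npv$hi,
        plr = r$plr$point, plr_lo = r$plr$lo, plr_hi = r$plr$hi,
        nlr = r$nlr$point, nlr_lo = r$nlr$lo, nlr_hi = r$nlr$hi)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.dx_comparison <- function(x, ...) {
  cat(sprintf(
    "Diagnostic accuracy for severe maternal morbidity (n = %d, %d morbid, prevalence %s)\n\n",
    x$n, x$n_morbid, fmt_percent_1dp(x$prevalence$point)))
  tab <- as.data.frame(x, formatted = TRUE)
  names(tab) <- c("Test", "Sensitivity", "Specificity", "PPV", "NPV",
                  "PLR", "NLR")
  print(tab, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' @export
summary.dx_comparison <- function(object, ...) {
  print(object)
  cat("\n2x2 counts (tp/fp/fn/tn):\n")
  for (r in object$reports)
    cat(sprintf("  %-22s %d/%d/%d/%d\n", r$label, r$matrix[["tp"]],
                r$matrix[["fp"]], r$matrix[["fn"]], r$matrix[["tn"]]))
  invisible(object)
}

#' Reference 2x2 counts of the source cohort
#'
#' The per-definition confusion matrices of the original 723-woman
#' postpartum cohort (24 with severe maternal morbidity), reconstructed by
#' integer enumeration from its published accuracy table: for each
#' definition, the unique cell counts over denominators 24 (morbid) and 699
#' (non-morbid) that reproduce every printed point estimate, with the four
#' exclusive obstetric strata partitioning the 699 non-morbid women as
#' 6 (red) + 259 (yellow) + 294 (green) + 140 (score 0).
#'
#' @return Named list of `confusion_matrix` objects: the six test
#'   definitions plus `meows_none` (the zero-score stratum).
#' @examples
#' diagnostic_report(reference_counts()$meows_red, "MEOWS red")
#' @export
reference_counts <- function() {
  list(
    meows_red_or_yellow = new_confusion_matrix(22, 265, 2, 434),
    meows_red = new_confusion_matrix(14, 6, 10, 693),
    meows_yellow = new_confusion_matrix(8, 259, 16, 440),
    meows_green = new_confusion_matrix(2, 294, 22, 405),
    ews_inform = new_confusion_matrix(15, 238, 9, 461),
    ews_emergency = new_confusion_matrix(2, 6, 22, 693),
    meows_none = new_confusion_matrix(0, 140, 24, 559)
  )
}

#' Evaluate the reference counts
#'
#' Runs the full accuracy computation on [reference_counts()], reproducing
#' the published comparison table without patient data.
#'
#' @param level Confidence level.
#' @return A `dx_comparison`.
#' @export
evaluate_reference <- function(level = 0.95) {
  defs <- test_definitions()
  counts <- reference_counts()
  reports <- lapply(names(defs), function(d)
    diagnostic_report(counts[[d]], defs[[d]], level))
  names(reports) <- names(defs)
  structure(list(reports = reports,
                 prevalence = clopper_pearson(24, 723, level),
                 n = 723, n_morbid = 24, level = level),
            class = "dx_comparison")
}
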