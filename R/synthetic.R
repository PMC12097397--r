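MORBIDITY_SUBTYPES <- c("hypertensive", "hemorrhage", "pulmonary",
                        "anesthesia")
DELIVERY_MODES <- c("vaginal", "planned_cesarean", "emergency_cesarean",
                    "operative_vaginal")

# clamp(round(normal draw)) into an integer band: guarantees the value lands
# inside [lo, hi] so a constructed observation scores exactly as intended.
r_band_int <- function(n, mean, sd, lo, hi) {
  pmin(pmax(round(stats::rnorm(n, mean, sd)), lo), hi)
}

r_band_dec <- function(n, mean, sd, lo, hi, digits = 1) {
  pmin(pmax(round_half_up(stats::rnorm(n, mean, sd), digits), lo), hi)
}

# Split-normal draw with the given median and quartiles (two half-normals
# glued at the median), clamped to [lo, hi]. Matches a skewed vital/covariate
# summary reported as median (Q1-Q3).
r_split_normal <- function(n, med, q1, q3, lo = -Inf, hi = Inf) {
  z75 <- stats::qnorm(0.75)
  sd_lo <- (med - q1) / z75
  sd_hi <- (q3 - med) / z75
  upper <- stats::runif(n) < 0.5
  x <- med + ifelse(upper, abs(stats::rnorm(n, 0, 1)) * sd_hi,
                    -abs(stats::rnorm(n, 0, 1)) * sd_lo)
  pmin(pmax(x, lo), hi)
}

# Blood loss in the severe-morbidity group is bimodal: moderate bleeds
# around the median and a massive-hemorrhage subgroup beyond the upper
# quartile. Below the median: half-normal matching Q1 = 300; above: half the
# upper mass stays within ~200 mL of the median, the other half is the
# massive-hemorrhage tail starting at Q3 = 1630. Median 500 and both
# quartiles hold exactly.
r_blood_loss_morbid <- function(n) {
  z75 <- stats::qnorm(0.75)
  upper <- stats::runif(n) < 0.5
  heavy <- stats::runif(n) < 0.5
  x <- 500 - abs(stats::rnorm(n, 0, (500 - 300) / z75))
  close_up <- upper & !heavy
  x[close_up] <- 500 + abs(stats::rnorm(sum(close_up), 0, 200))
  tail_up <- upper & heavy
  x[tail_up] <- 1630 + abs(stats::rnorm(sum(tail_up), 0, 800))
  pmin(pmax(x, 50), 6000)
}

#' Configuration of the synthetic postpartum cohort
#'
#' Defaults encode the study conditions: 723 women monitored in an obstetric
#' high-dependency unit for 48 hours (observations every 4 h), severe
#' maternal morbidity prevalence 24/723, morbidity cause mixture
#' hypertensive 13/24, hemorrhage 8/24, pulmonary 2/24, anesthesia 1/24, and
#' the worst-category frequencies of the reconstructed accuracy table:
#' morbid women reach red/yellow/green/none with probability 14/24, 8/24,
#' 2/24, 0 and non-morbid women with 6/699, 259/699, 294/699, 140/699.
#' General-EWS alert margins (inform 15/24 and 238/699, emergency 2/24 and
#' 6/699) are targeted best-effort through a separate low-grade-abnormality
#' observation; the joint distribution of the two charts is not identified
#' by the published margins.
#'
#' @param n_women Cohort size.
#' @param prevalence Probability of severe maternal morbidity.
#' @param subtype_mix Named probabilities over morbidity causes.
#' @param meows_probs_morbid,meows_probs_nonmorbid Named probabilities of
#'   the worst obstetric category (`none`, `green`, `yellow`, `red`).
#' @param ews_probs_morbid,ews_probs_nonmorbid Named probabilities of the
#'   targeted general-chart alert level (`none`, `inform`, `emergency`).
#' @param schedule Observation times in hours since admission.
#' @param max_attempts Regeneration attempts before an infeasible-target
#'   error.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(
    n_women = 723,
    prevalence = 24 / 723,
    subtype_mix = c(hypertensive = 13, hemorrhage = 8, pulmonary = 2,
                    anesthesia = 1) / 24,
    meows_probs_morbid = c(none = 0, green = 2, yellow = 8, red = 14) / 24,
    meows_probs_nonmorbid = c(none = 140, green = 294, yellow = 259,
                              red = 6) / 699,
    ews_probs_morbid = c(none = 9, inform = 13, emergency = 2) / 24,
    ews_probs_nonmorbid = c(none = 461, inform = 232, emergency = 6) / 699,
    schedule = seq(0, 48, by = 4),
    max_attempts = 10) {
  chk <- function(p, nm) {
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0) || any(p > 1))
      stop(nm, " must be probabilities summing to 1")
  }
  chk(subtype_mix, "subtype_mix")
  chk(meows_probs_morbid, "meows_probs_morbid")
  chk(meows_probs_nonmorbid, "meows_probs_nonmorbid")
  chk(ews_probs_morbid, "ews_probs_morbid")
  chk(ews_probs_nonmorbid, "ews_probs_nonmorbid")
  stopifnot(prevalence >= 0, prevalence <= 1, n_women >= 1,
            length(schedule) >= 1)
  structure(list(n_women = n_women, prevalence = prevalence,
                 subtype_mix = subtype_mix,
                 meows_probs_morbid = meows_probs_morbid,
                 meows_probs_nonmorbid = meows_probs_nonmorbid,
                 ews_probs_morbid = ews_probs_morbid,
                 ews_probs_nonmorbid = ews_probs_nonmorbid,
                 schedule = schedule, max_attempts = max_attempts),
            class = "cohort_config")
}

# All-normal observation block: every value sits in the zero-score region of
# BOTH charts, so baselines contribute nothing to either worst category.
baseline_block <- function(n) {
  data.frame(
    resp_rate = r_band_int(n, 13.5, 1.0, 12, 14),
    spo2 = r_band_int(n, 98, 1.3, 96, 100),
    o2_supplement = rep(FALSE, n),
    temperature = r_band_dec(n, 36.9, 0.18, 36.6, 37.2),
    sbp = r_band_int(n, 119, 9, 101, 139),
    dbp = r_band_int(n, 72, 8, 55, 89),
    heart_rate = r_band_int(n, 80, 9, 61, 100),
    avpu = rep("A", n),
    vas_pain = sample(0:3, n, replace = TRUE,
                      prob = c(0.45, 0.3, 0.15, 0.1)))
}

# Overwrite one observation per woman with a deteriorated-parameter pattern
# whose obstetric score lands exactly in the target category. Patterns follow
# the morbidity cause: hypertensive -> blood pressure, hemorrhage ->
# tachycardia/hypotension/desaturation, pulmonary -> respiratory rate/SpO2/
# oxygen, anesthesia -> consciousness/pain.
apply_peaks <- function(block, target, subtype, yellow_route) {
  k <- nrow(block)
  stopifnot(length(target) == k)
  set_rows <- function(mask, col, values) {
    if (any(mask)) block[mask, col] <<- values
    invisible(NULL)
  }
  for (st in MORBIDITY_SUBTYPES) {
    g <- target == "green" & subtype == st
    n <- sum(g)
    if (n) switch(st,
      hypertensive = {
        set_rows(g, "sbp", r_band_int(n, 144, 3, 140, 149))
        half <- g & stats::runif(k) < 0.5
        set_rows(half, "dbp", r_band_int(sum(half), 94, 3, 90, 99))
      },
      hemorrhage = {
        set_rows(g, "heart_rate", r_band_int(n, 105, 3, 101, 109))
        set_rows(g, "vas_pain", sample(4:6, n, replace = TRUE))
      },
      pulmonary = set_rows(g, "spo2", r_band_int(n, 93, 1.2, 92, 95)),
      anesthesia = set_rows(g, "vas_pain", sample(4:6, n, replace = TRUE)))

    y3 <- target == "yellow" & subtype == st & yellow_route
    n <- sum(y3)
    if (n) switch(st,  # single 3-point parameter, total <= 4
      hypertensive = set_rows(y3, "dbp", r_band_int(n, 115, 3, 111, 122)),
      hemorrhage = set_rows(y3, "sbp", r_band_int(n, 85, 3, 81, 89)),
      pulmonary = set_rows(y3, "spo2", r_band_int(n, 89, 1.5, 87, 91)),
      anesthesia = set_rows(y3, "avpu", rep("V", n)))

    y56 <- target == "yellow" & subtype == st & !yellow_route
    n <- sum(y56)
    if (n) switch(st,  # total 5-6 from 1/2-point bands, no 3s
      hypertensive = {
        set_rows(y56, "sbp", r_band_int(n, 155, 2.5, 151, 159))
        set_rows(y56, "dbp", r_band_int(n, 105, 2.5, 101, 109))
        set_rows(y56, "vas_pain", sample(4:6, n, replace = TRUE))
      },
      hemorrhage = {
        set_rows(y56, "spo2", r_band_int(n, 93, 1.2, 92, 95))
        set_rows(y56, "vas_pain", sample(4:6, n, replace = TRUE))
        set_rows(y56, "o2_supplement", rep(TRUE, n))
      },
      pulmonary = {
        set_rows(y56, "resp_rate", r_band_int(n, 23, 1.2, 21, 25))
        set_rows(y56, "spo2", r_band_int(n, 93, 1.2, 92, 95))
        set_rows(y56, "o2_supplement", rep(TRUE, n))
      },
      anesthesia = {
        set_rows(y56, "vas_pain", sample(4:6, n, replace = TRUE))
        set_rows(y56, "temperature", r_band_dec(n, 37.4, 0.08, 37.3, 37.5))
        set_rows(y56, "dbp", r_band_int(n, 105, 2.5, 101, 109))
      })

    r <- target == "red" & subtype == st
    n <- sum(r)
    if (n) switch(st,  # one or two 3-point parameters, total >= 7
      hypertensive = {
        set_rows(r, "sbp", r_band_int(n, 172, 8, 162, 195))
        set_rows(r, "dbp", r_band_int(n, 116, 4, 111, 125))
        set_rows(r, "vas_pain", sample(4:6, n, replace = TRUE))
      },
      hemorrhage = {
        set_rows(r, "heart_rate", r_band_int(n, 138, 5, 131, 155))
        set_rows(r, "spo2", r_band_int(n, 93, 1.2, 92, 95))
        set_rows(r, "vas_pain", sample(4:6, n, replace = TRUE))
      },
      pulmonary = {
        set_rows(r, "resp_rate", r_band_int(n, 30, 2.5, 26, 38))
        set_rows(r, "spo2", r_band_int(n, 89, 1.8, 85, 91))
        set_rows(r, "o2_supplement", rep(TRUE, n))
      },
      anesthesia = {
        set_rows(r, "avpu", rep("P", n))
        set_rows(r, "vas_pain", sample(7:10, n, replace = TRUE))
        set_rows(r, "heart_rate", r_band_int(n, 114, 3, 110, 119))
      })
  }
  block
}

# Low-grade abnormalities that score on the general chart but 0 on the
# obstetric one: mild hypothermia + upper-normal respiratory rate (2 points,
# "inform"), plus mild tachycardia and borderline systolic pressure for the
# 4-point "emergency" pattern.
apply_ews_nudge <- function(block, level) {
  k <- nrow(block)
  stopifnot(length(level) == k)
  m <- level != "none"
  n <- sum(m)
  if (n) {
    block[m, "temperature"] <- r_band_dec(n, 36.35, 0.12, 36.1, 36.5)
    block[m, "resp_rate"] <- r_band_int(n, 17, 1.5, 15, 20)
  }
  e <- level == "emergency"
  n <- sum(e)
  if (n) {
    block[e, "heart_rate"] <- r_band_int(n, 105, 3, 101, 109)
    block[e, "sbp"] <- r_band_int(n, 95, 3, 90, 100)
  }
  block
}

# Build the long observation table for one set of per-woman assignments.
build_observations <- function(ids, target, subtype, ews_target, schedule) {
  n <- length(ids)
  n_obs <- length(schedule)
  obs <- baseline_block(n * n_obs)
  obs$woman_id <- rep(ids, each = n_obs)
  obs$timestamp <- rep(schedule, times = n)

  row0 <- (seq_len(n) - 1) * n_obs
  peak_slot <- sample.int(n_obs, n, replace = TRUE)
  has_peak <- target != "none"
  peak_rows <- row0[has_peak] + peak_slot[has_peak]
  yellow_route <- stats::runif(n) < 0.5
  if (any(has_peak)) {
    obs[peak_rows, ] <- cbind(
      apply_peaks(obs[peak_rows, VITAL_PARAMETERS, drop = FALSE],
                  target[has_peak], subtype[has_peak],
                  yellow_route[has_peak]),
      obs[peak_rows, c("woman_id", "timestamp"), drop = FALSE])
  }
  if (n_obs > 1) {
    nudge_slot <- peak_slot %% n_obs + 1
    has_nudge <- ews_target != "none"
    nudge_rows <- row0[has_nudge] + nudge_slot[has_nudge]
    if (any(has_nudge)) {
      obs[nudge_rows, ] <- cbind(
        apply_ews_nudge(
          obs[nudge_rows, VITAL_PARAMETERS, drop = FALSE],
          ews_target[has_nudge]),
        obs[nudge_rows, c("woman_id", "timestamp"), drop = FALSE])
    }
  }
  obs[c("woman_id", "timestamp", VITAL_PARAMETERS)]
}

#' Draw covariates for synthetic women
#'
#' Skewed continuous covariates are drawn from split-normal distributions
#' matching the reported median and interquartile range per outcome group
#' (gestational age, body-mass index, blood loss); length of stay from a
#' discrete distribution with the reported median/IQR/range; binary and
#' categorical covariates at the reported group proportions.
#'
#' @param morbid Logical: draw from the severe-morbidity group?
#' @param n Number of women.
#' @param seed Optional seed for a self-contained draw.
#' @return Data frame with columns `age`, `bmi_prepregnancy`,
#'   `bmi_delivery`, `gestational_age`, `nulliparity`, `twin_pregnancy`,
#'   `delivery_mode`, `blood_loss_ml`, `days_hdu`.
#' @export
sample_covariates <- function(morbid, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (morbid) {
    days_p <- c(0, 0.15, 0.40, 0.25, 0.10, 0.05, 0.02, 0.015, 0.01, 0.005)
    out <- data.frame(
      age = round(r_split_normal(n, 30.5, 28.0, 33.5, 16, 52)),
      bmi_prepregnancy = round_half_up(
        r_split_normal(n, 23.6, 21.3, 28.8, 15, 55), 1),
      bmi_delivery = round_half_up(
        r_split_normal(n, 30.1, 25.9, 35.7, 17, 60), 1),
      gestational_age = round_half_up(
        r_split_normal(n, 36.8, 31.5, 38.5, 22, 42.5), 1),
      nulliparity = stats::runif(n) < 17 / 24,
      twin_pregnancy = stats::runif(n) < 2 / 24,
      delivery_mode = sample(DELIVERY_MODES, n, replace = TRUE,
                             prob = c(5, 3, 16, 0) / 24),
      blood_loss_ml = round_half_up(r_blood_loss_morbid(n), -1),
      days_hdu = sample(seq_along(days_p), n, replace = TRUE, prob = days_p))
  } else {
    days_p <- c(0.12, 0.70, 0.10, 0.04, 0.015, 0.01, 0.005, 0.004, 0.003,
                0.002, 0.001)
    out <- data.frame(
      age = round(r_split_normal(n, 32.0, 28.0, 35.0, 16, 52)),
      bmi_prepregnancy = round_half_up(
        r_split_normal(n, 23.9, 21.4, 27.5, 15, 55), 1),
      bmi_delivery = round_half_up(
        r_split_normal(n, 29.2, 26.4, 32.7, 17, 60), 1),
      gestational_age = round_half_up(
        r_split_normal(n, 39.1, 38.0, 40.0, 22, 42.5), 1),
      nulliparity = stats::runif(n) < 367 / 699,
      twin_pregnancy = stats::runif(n) < 31 / 699,
      delivery_mode = sample(DELIVERY_MODES, n, replace = TRUE,
                             prob = c(117, 252, 321, 9) / 699),
      blood_loss_ml = round_half_up(
        r_split_normal(n, 400, 300, 500, 50, 5000), -1),
      days_hdu = sample(seq_along(days_p), n, replace = TRUE, prob = days_p))
  }
  out
}

#' Generate a seeded synthetic postpartum cohort
#'
#' Draws morbidity at the configured prevalence, assigns every woman a
#' target worst obstetric category from her outcome group's frequency table
#' and a morbidity-cause profile, and constructs a 48-hour observation
#' series whose scored worst category is exactly the target: baseline
#' observations sit in the zero-score region of both charts and one
#' deteriorated observation carries the cause-consistent abnormal pattern.
#' Every stay is re-scored after construction; any woman whose worst
#' category misses her target is regenerated (bounded attempts).
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the cohort is fully reproducible given
#'   `config` and `seed`.
#' @return A `cohort_table` data frame in the long schema of
#'   [cohort_schema()], with hidden per-woman attributes dropped -- the
#'   generative targets are recoverable only by re-scoring, as in real data.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_women = 50), seed = 42)
#' assess_cohort(cohort)
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_women
  ids <- sprintf("W%04d", seq_len(n))
  morbid <- stats::runif(n) < config$prevalence
  subtype <- sample(names(config$subtype_mix), n, replace = TRUE,
                    prob = config$subtype_mix)
  draw_cat <- function(m, probs_m, probs_nm) {
    out <- character(n)
    if (any(m))
      out[m] <- sample(names(probs_m), sum(m), replace = TRUE,
                       prob = probs_m)
    if (any(!m))
      out[!m] <- sample(names(probs_nm), sum(!m), replace = TRUE,
                        prob = probs_nm)
    out
  }
  target <- draw_cat(morbid, config$meows_probs_morbid,
                     config$meows_probs_nonmorbid)
  ews_target <- draw_cat(morbid, config$ews_probs_morbid,
                         config$ews_probs_nonmorbid)

  meows <- build_meows_system()
  obs <- build_observations(ids, target, subtype, ews_target,
                            config$schedule)
  # verify the generative contract and regenerate any misses
  for (attempt in seq_len(config$max_attempts)) {
    sc <- score_cohort(obs, meows)
    worst <- tapply(as.integer(meows_triage(sc$total, sc$max_single)),
                    factor(obs$woman_id, levels = ids), max)
    bad <- MEOWS_CATEGORIES[worst] != target
    if (!any(bad)) break
    if (attempt == config$max_attempts)
      stop("infeasible category targets: ", sum(bad),
           " stays failed to realise their target after ",
           config$max_attempts, " attempts")
    redo <- build_observations(ids[bad], target[bad], subtype[bad],
                               ews_target[bad], config$schedule)
    obs <- rbind(obs[!obs$woman_id %in% ids[bad], ], redo)
    obs <- obs[order(match(obs$woman_id, ids), obs$timestamp), ]
  }

  cov <- rbind_groups(morbid)
  per_woman <- cbind(data.frame(woman_id = ids, morbidity = morbid,
                                morbidity_cause = ifelse(morbid, subtype,
                                                         NA_character_)),
                     cov)
  out <- cbind(obs, per_woman[match(obs$woman_id, per_woman$woman_id),
                              -1, drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

# covariates drawn group-wise but returned in woman order
rbind_groups <- function(morbid) {
  n <- length(morbid)
  cm <- sample_covariates(TRUE, sum(morbid))
  cn <- sample_covariates(FALSE, sum(!morbid))
  idx <- integer(n)
  idx[morbid] <- seq_len(sum(morbid))
  idx[!morbid] <- sum(morbid) + seq_len(sum(!morbid))
  out <- rbind(cm, cn)[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Draw a single observation realising a target triage category
#'
#' Constructs one observation whose obstetric score maps exactly to the
#' requested category, with the deteriorated parameters chosen according to
#' the morbidity cause, and verifies it by re-scoring (rejection sampling
#' with a bounded budget).
#'
#' @param target One of `"none"`, `"green"`, `"yellow"`, `"red"`.
#' @param subtype One of `"hypertensive"`, `"hemorrhage"`, `"pulmonary"`,
#'   `"anesthesia"`.
#' @param max_attempts Rejection budget.
#' @param seed Optional seed.
#' @return A one-row data frame of the nine vital-sign fields.
#' @export
sample_observation_for_category <- function(target,
                                            subtype = "hypertensive",
                                            max_attempts = 100,
                                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  target <- match.arg(target, MEOWS_CATEGORIES)
  subtype <- match.arg(subtype, MORBIDITY_SUBTYPES)
  meows <- build_meows_system()
  for (attempt in seq_len(max_attempts)) {
    block <- baseline_block(1)
    if (target != "none")
      block <- apply_peaks(block, target, subtype,
                           yellow_route = stats::runif(1) < 0.5)
    sc <- score_cohort(block, meows)
    if (as.character(meows_triage(sc$total, sc$max_single)) == target)
      return(block)
  }
  stop("rejection budget exhausted for target '", target, "' (", subtype,
       ")")
}
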