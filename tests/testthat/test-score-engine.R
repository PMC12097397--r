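meows <- build_meows_system()
ews <- build_ews_system()

test_that("MEOWS chart encodes the printed bands", {
  expect_equal(score_parameter(165, meows$rules$sbp), 3L)
  expect_equal(score_parameter(36.5, meows$rules$temperature), 0L)
  expect_equal(score_parameter(125, meows$rules$heart_rate), 2L)
  expect_equal(score_parameter("A", meows$rules$avpu), 0L)
  expect_equal(score_parameter(c("V", "P", "U"), meows$rules$avpu),
               c(3L, 3L, 3L))
  expect_equal(score_parameter(TRUE, meows$rules$o2_supplement), 2L)
  expect_equal(score_parameter(FALSE, meows$rules$o2_supplement), 0L)
  # boundary values in two overlapping bands take the higher score
  expect_equal(score_parameter(150, meows$rules$sbp), 2L)
  expect_equal(score_parameter(160, meows$rules$sbp), 2L)
  expect_equal(score_parameter(7, meows$rules$vas_pain), 3L)
  expect_equal(score_parameter(120, meows$rules$heart_rate), 2L)
  expect_equal(score_parameter(60, meows$rules$heart_rate), 2L)
})

test_that("EWS chart encodes the printed bands, including its gaps", {
  expect_equal(score_parameter("P", ews$rules$avpu), 2L)
  expect_equal(score_parameter(37.0, ews$rules$temperature), 0L)
  expect_equal(score_parameter(40, ews$rules$heart_rate), 0L)
  expect_equal(score_parameter(130, ews$rules$heart_rate), 0L)
  expect_equal(score_parameter(30, ews$rules$resp_rate), 0L)
  expect_equal(score_parameter(131, ews$rules$heart_rate), 3L)
  # the temperature row has no 3-point band as printed
  maxpts <- max(vapply(ews$rules$temperature$bands, `[[`, 0L, "points"))
  expect_equal(maxpts, 2L)
})

test_that("band lookup agrees with the brute-force oracle on a grid", {
  grids <- list(resp_rate = seq(0, 60, 0.5), heart_rate = seq(0, 220, 0.5),
                sbp = seq(40, 260, 0.5), dbp = seq(20, 160, 0.5),
                temperature = seq(33, 42, 0.1), spo2 = seq(50, 100, 0.5),
                vas_pain = seq(0, 10, 0.5))
  for (system in list(meows, ews)) {
    for (rule in system$rules) {
      if (rule$type != "numeric") next
      g <- grids[[rule$parameter]]
      expect_equal(score_parameter(g, rule), oracle_score(g, rule),
                   info = paste(system$name, rule$parameter))
    }
  }
})

test_that("non-finite numeric values are rejected", {
  expect_error(score_parameter(NaN, meows$rules$sbp), "non-finite")
  expect_error(score_parameter(Inf, meows$rules$heart_rate), "non-finite")
  expect_error(score_parameter("X", meows$rules$avpu), "AVPU")
})

test_that("observation scoring sums the per-parameter points", {
  s <- score_observation(normal_obs(), meows)
  expect_equal(s$total, 0L)
  expect_equal(s$n_missing, 0L)

  s <- score_observation(list(resp_rate = 23, spo2 = 93, o2_supplement = TRUE,
                              temperature = 37.5, sbp = 145, dbp = 95,
                              heart_rate = 115, avpu = "A", vas_pain = 5),
                         meows)
  expect_equal(unname(s$per_parameter),
               c(2L, 2L, 2L, 2L, 1L, 1L, 1L, 0L, 2L))
  expect_equal(s$total, 13L)
  expect_equal(s$max_single, 2L)

  s <- score_observation(list(heart_rate = 105, sbp = 95, resp_rate = 18,
                              temperature = 37.8, avpu = "A"), ews)
  expect_equal(s$total, 4L)
})

test_that("missing parameters score 0, are counted, and never raise totals", {
  s <- score_observation(normal_obs(sbp = NA, vas_pain = NA), meows)
  expect_equal(s$n_missing, 2L)
  expect_error(
    score_observation(as.list(stats::setNames(rep(NA, 9),
                                              names(meows$rules))), meows),
    "empty observation")

  # dropping any single value never increases the total
  set.seed(41)
  for (i in 1:25) {
    obs <- normal_obs(sbp = sample(60:220, 1), heart_rate = sample(30:180, 1),
                      resp_rate = sample(5:40, 1), vas_pain = sample(0:10, 1))
    full <- score_observation(obs, meows)$total
    for (p in names(meows$rules)) {
      reduced <- obs
      reduced[[p]] <- NA
      expect_lte(score_observation(reduced, meows)$total, full)
    }
  }
})

test_that("totals are invariant to parameter order and equal the rule sums", {
  set.seed(7)
  for (i in 1:20) {
    obs <- normal_obs(sbp = sample(60:220, 1), dbp = sample(40:140, 1),
                      heart_rate = sample(30:180, 1),
                      temperature = round(runif(1, 34, 41), 1))
    shuffled <- obs[sample(names(obs))]
    s1 <- score_observation(obs, meows)
    s2 <- score_observation(shuffled, meows)
    expect_equal(s1$total, s2$total)
    expect_equal(s1$total, sum(vapply(names(meows$rules), function(p)
      score_parameter(obs[[p]], meows$rules[[p]]), integer(1))))
    expect_equal(s1$max_single, max(s1$per_parameter))
  }
})

test_that("per-parameter scores stay within each chart's printed range", {
  set.seed(11)
  block <- data.frame(
    resp_rate = sample(5:45, 200, TRUE), spo2 = sample(70:100, 200, TRUE),
    o2_supplement = sample(c(TRUE, FALSE), 200, TRUE),
    temperature = round(runif(200, 34, 41), 1),
    sbp = sample(60:230, 200, TRUE), dbp = sample(40:140, 200, TRUE),
    heart_rate = sample(30:180, 200, TRUE),
    avpu = sample(c("A", "V", "P", "U"), 200, TRUE,
                  prob = c(0.9, 0.05, 0.03, 0.02)),
    vas_pain = sample(0:10, 200, TRUE))
  sm <- score_cohort(block, meows)
  expect_true(all(as.matrix(sm[paste0("pts_", names(meows$rules))]) %in% 0:3))
  se <- score_cohort(block, ews)
  expect_true(all(se$pts_temperature %in% 0:2))
})

test_that("validation reports range violations and chart gaps", {
  expect_equal(nrow(validate_observation(normal_obs())), 0L)
  iss <- validate_observation(normal_obs(spo2 = 101))
  expect_equal(iss$parameter, "spo2")
  expect_equal(iss$kind, "range")
  iss <- validate_observation(normal_obs(heart_rate = 40), ews)
  expect_true("band_gap" %in% iss$kind)
  expect_true(any(iss$parameter == "heart_rate"))
  # a normal temperature is in the EWS zero region, not a gap
  expect_equal(nrow(validate_observation(normal_obs(temperature = 37), ews)),
               0L)
  iss <- validate_observation(normal_obs(sbp = -5, temperature = NaN))
  expect_setequal(iss$parameter, c("sbp", "temperature"))
})

test_that("charts round-trip through the YAML config bit-exactly", {
  for (system in list(meows, ews)) {
    path <- withr::local_tempfile(fileext = ".yaml")
    write_scoring_system(system, path)
    expect_identical(read_scoring_system(path), system)
  }
  shipped <- system.file("extdata", "meows.yaml", package = "ewstriage")
  expect_identical(read_scoring_system(shipped), meows)
})
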