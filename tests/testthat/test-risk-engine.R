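test_that("the published worked profile is reproduced from the fixture", {
  # woman, 61 years, TC 180 mg/dL, HDL 47, SBP 124 untreated, smoker,
  # non-diabetic: published 10-year general-CVD risk 10.48%.
  prof <- tibble::tibble(sex = "female", age_years = 61, tc = 180, hdl = 47,
                         sbp = 124, sbp_rx = FALSE, diabetic = FALSE,
                         smoker = TRUE)
  p <- framingham_risk(prof, default_risk_params(), 10)

  # independent hand computation of the linear predictor from the fixture
  lp <- 2.32888 * log(61) + 1.20904 * log(180) - 0.70833 * log(47) +
    2.76157 * log(124) + 0.52873
  expect_equal(as.numeric(p), 1 - 0.95012^exp(lp - 26.1931), tolerance = 1e-12)
  expect_equal(as.numeric(p), 0.1048, tolerance = 2e-3)
})

test_that("a profile at the sex-specific mean linear predictor has risk 1 - S0", {
  params <- default_risk_params()
  prof <- tibble::tibble(sex = "male", age_years = 55, tc = 213, hdl = 50,
                         sbp = 130, sbp_rx = FALSE, diabetic = FALSE,
                         smoker = FALSE)
  lp <- 3.06117 * log(55) + 1.12370 * log(213) - 0.93263 * log(50) +
    1.93303 * log(130)
  # shift the fixture's mean LP onto this profile: exponent becomes 1
  params$coefficients$beta[params$coefficients$sex == "male" &
                             params$coefficients$term == "mean_lp"] <- lp
  expect_equal(as.numeric(framingham_risk(prof, params, 10)),
               1 - 0.88936, tolerance = 1e-12)
})

test_that("risk is monotone in each risk factor with the expected sign", {
  base <- tibble::tibble(sex = c("male", "female"), age_years = 55, tc = 210,
                         hdl = 50, sbp = 130, sbp_rx = FALSE,
                         diabetic = FALSE, smoker = FALSE)
  p0 <- framingham_risk(base)
  bump <- function(col, value) {
    b <- base; b[[col]] <- value
    framingham_risk(b)
  }
  expect_true(all(bump("age_years", 65) > p0))
  expect_true(all(bump("sbp", 150) > p0))
  expect_true(all(bump("tc", 260) > p0))
  expect_true(all(bump("smoker", TRUE) > p0))
  expect_true(all(bump("diabetic", TRUE) > p0))
  expect_true(all(bump("hdl", 65) < p0))
})

test_that("5-year risk is hazard-scaled from the 10-year risk", {
  prof <- tibble::tibble(sex = "female", age_years = 61, tc = 180, hdl = 47,
                         sbp = 124, sbp_rx = FALSE, diabetic = FALSE,
                         smoker = TRUE)
  p10 <- as.numeric(framingham_risk(prof, horizon_years = 10))
  p5 <- framingham_risk(prof, horizon_years = 5)
  expect_equal(as.numeric(p5), 1 - (1 - p10)^0.5, tolerance = 1e-12)
  expect_equal(attr(p5, "horizon_method"), "hazard_scaled_from_10y")
  expect_error(framingham_risk(prof, horizon_years = 7), "5 or 10")
})

test_that("annualize applies the constant-hazard conversion and inverts", {
  expect_equal(annualize(0, 10), 0)
  expect_equal(annualize(0.37, 1), 0.37)
  expect_equal(annualize(0.10, 10), 0.0104807418, tolerance = 1e-9)
  for (p in c(0.01, 0.1, 0.5, 0.9)) {
    for (h in c(2, 5, 10)) {
      expect_equal(1 - (1 - annualize(p, h))^h, p, tolerance = 1e-12)
    }
  }
  expect_error(annualize(1, 10), "infinite hazard")
})

test_that("FRS banding uses inclusive thresholds", {
  expect_equal(as.character(frs_band(c(0.10, 0.15, 0.151, 0.05, 0.3))),
               c("low", "medium", "high", "low", "high"))
  # low-risk programme variant: eligibility cut at 10%
  expect_equal(as.character(frs_band(0.10, c(low = 0.05, medium = 0.10))),
               "medium")
})

test_that("PRS decomposition matches an independent root-finding oracle", {
  d <- decompose_by_prs(0.05, 1.9, 0.2)
  expect_equal(d$p_high, 0.0784554668, tolerance = 1e-8)
  expect_equal(d$p_low, 0.0428861333, tolerance = 1e-8)

  set.seed(11)
  for (i in 1:20) {
    p <- runif(1, 0.001, 0.6)
    or <- runif(1, 0.5, 3)
    f <- runif(1, 0.05, 0.6)
    got <- decompose_by_prs(p, or, f)
    want <- decompose_oracle(p, or, f)
    expect_equal(got$p_high, unname(want["p_high"]), tolerance = 1e-9)
    expect_equal(got$p_low, unname(want["p_low"]), tolerance = 1e-9)
  }
})

test_that("PRS decomposition invariants hold over a parameter sweep", {
  p <- rep(seq(0.005, 0.8, by = 0.005), times = 3)
  f <- rep(c(0.1, 0.2, 0.5), each = length(p) / 3)
  for (or in c(1.2, 1.8, 1.9, 2.0, 3)) {
    d <- decompose_by_prs(p, or, 0.2)
    # mixture recombines to p; realized odds ratio equals the input
    expect_equal(0.2 * d$p_high + 0.8 * d$p_low, p, tolerance = 1e-12)
    odds <- function(x) x / (1 - x)
    expect_equal(odds(d$p_high) / odds(d$p_low), rep(or, length(p)),
                 tolerance = 1e-9)
    expect_true(all(d$p_low < p & p < d$p_high))
  }
  d1 <- decompose_by_prs(c(0, 0.04), 1.9, 0.2)
  expect_equal(d1$p_high[1], 0)
  expect_equal(d1$p_low[1], 0)
  dunit <- decompose_by_prs(0.04, 1, 0.2)
  expect_equal(dunit$p_high, 0.04, tolerance = 1e-12)
  expect_equal(dunit$p_low, 0.04, tolerance = 1e-12)
})

test_that("statin treatment maps high-PRS risk to the non-top-quintile risk", {
  expect_equal(treated_high_prs_risk(0.080, 0.042), 0.042)
  expect_equal(treated_high_prs_risk(0.05, 0.05), 0.05)
  expect_equal(treated_high_prs_risk(0.080, 0.042, mode = "rrr", rrr = 0.47),
               0.080 * 0.53)
  expect_error(treated_high_prs_risk(0.03, 0.05), "inconsistent")
})

test_that("secondary-prevention risk scales the primary risk with clipping", {
  expect_equal(secondary_risk(0.02, 1), 0.02)
  expect_equal(secondary_risk(0.02, 2), 0.04)
  expect_equal(secondary_risk(0.8, 2), 1)
  expect_error(secondary_risk(0.02, 0.5), ">= 1")
})

test_that("calibration multipliers reproduce observed events in one step", {
  params <- default_params_fixture()
  st <- synthesize_population(params, 1e6, seed = 2)
  risks <- cell_risks(st, params)
  modeled <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(sex = as.character(st$sex),
                     age_band = as.character(st$age_band),
                     ev = st$primary_pool * risks$p_annual),
      sex, age_band),
    events = sum(ev), .groups = "drop")

  expect_equal(calibrate(modeled, modeled)$multiplier, rep(1, 12))
  twice <- dplyr::mutate(modeled, events = 2 * events)
  expect_equal(calibrate(twice, modeled)$multiplier, rep(2, 12))

  # fixed point: rescale to arbitrary observed totals and re-simulate
  obs <- dplyr::mutate(modeled, events = events *
                         seq(0.5, 1.6, length.out = 12))
  params$risk$calibration <- calibrate(obs, modeled)
  risks2 <- cell_risks(st, params)
  re <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(sex = as.character(st$sex),
                     age_band = as.character(st$age_band),
                     ev = st$primary_pool * risks2$p_annual),
      sex, age_band),
    events = sum(ev), .groups = "drop")
  expect_equal(re$events, obs$events, tolerance = 0.01)

  zero <- dplyr::mutate(modeled, events = ifelse(sex == "male" &
                                                   age_band == "20-34",
                                                 0, events))
  expect_warning(calibrate(obs, zero), "multiplier left at 1")
})
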