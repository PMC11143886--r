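test_that("the OHCA split follows the stated arithmetic", {
  e <- default_event_params()
  e$ohca_fraction <- 0
  sp <- split_ohca(100, e)
  expect_equal(sp$ohca_events, 0)
  expect_equal(sp$hospitalised, 100)

  e$ohca_fraction <- 0.1
  e$ohca_initial_survival <- 0.3
  e$thirty_day_mortality <- 0.1
  sp <- split_ohca(100, e)
  expect_equal(sp$ohca_events, 10)
  expect_equal(sp$ohca_deaths, 7)
  expect_equal(sp$ohca_survivors, 3)
  expect_equal(sp$hospitalised, 90)
  expect_equal(sp$hospital_deaths, 9)
  expect_equal(sp$hospital_survivors, 81)

  sp0 <- split_ohca(0, e)
  expect_true(all(unlist(sp0) == 0))
  expect_error(split_ohca(-1, e))
})

test_that("high-risk mortality applies the sex/OHCA multipliers", {
  expect_equal(high_risk_mortality(1000, "male", FALSE, 0.02), 28.5)
  expect_equal(high_risk_mortality(1000, "female", FALSE, 0.02), 29.9)
  expect_equal(high_risk_mortality(1000, "male", TRUE, 0.02), 78)
  expect_equal(high_risk_mortality(1000, "female", TRUE, 0.02), 78)
  # multiplier-1 override recovers base deaths; product is clipped at 1
  unit <- c(male_non_ohca = 1, female_non_ohca = 1, ohca_any_sex = 1)
  expect_equal(high_risk_mortality(1000, "male", FALSE, 0.02, unit), 20)
  expect_equal(high_risk_mortality(100, "male", TRUE, 0.5), 100)
  expect_error(high_risk_mortality(10, "other", FALSE, 0.02), "unknown sex")
})

test_that("the two-year recurrence risk is annualized by constant hazard", {
  expect_equal(annual_recurrence_prob(0), 0)
  expect_equal(annual_recurrence_prob(0.25), 1 - sqrt(0.75), tolerance = 1e-12)
  expect_equal(annual_recurrence_prob(0.25), 0.1339745962, tolerance = 1e-9)
  a <- annual_recurrence_prob(0.25)
  expect_equal(1 - (1 - a)^2, 0.25, tolerance = 1e-12)
  expect_error(annual_recurrence_prob(1))
})

test_that("graduation conserves persons and shifts the high-risk stocks", {
  st <- toy_state(5, y1_ohca = 10, y1_non = 20, y2_ohca = 3, y2_non = 7,
                  prior_chd = 100)
  g <- graduate(st)
  expect_equal(g$prior_chd[5], 110)
  expect_equal(g$post_ace_y2_ohca[5], 10)
  expect_equal(g$post_ace_y2_nonohca[5], 20)
  expect_equal(g$post_ace_y1_ohca[5] + g$post_ace_y1_nonohca[5], 0)
  expect_equal(total_persons(g), total_persons(st))

  empty <- toy_state(5, primary = 50)
  expect_equal(tibble::as_tibble(graduate(empty)), tibble::as_tibble(empty))
})

test_that("incident events recombine the PRS mixture consistently", {
  d <- decompose_by_prs(0.05, 1.9, 0.2)
  treated <- treated_high_prs_risk(d$p_high, d$p_low)
  # zero coverage: events equal persons times the undecomposed risk
  expect_equal(incident_aces(1000, d$p_high, d$p_low, treated, 0.2, 0),
               1000 * 0.05, tolerance = 1e-9)
  # full coverage of the top quintile: everyone at the non-top risk
  expect_equal(incident_aces(1000, d$p_high, d$p_low, treated, 0.2, 200),
               1000 * d$p_low, tolerance = 1e-9)
  # 50% coverage: brute-force four-stratum enumeration
  manual <- 100 * treated + 100 * d$p_high + 800 * d$p_low
  expect_equal(incident_aces(1000, d$p_high, d$p_low, treated, 0.2, 100),
               manual, tolerance = 1e-12)
  expect_error(incident_aces(1000, d$p_high, d$p_low, treated, 0.2, 300),
               "exceed")
})

test_that("simulation is deterministic and a null scenario equals baseline", {
  params <- default_params_fixture()
  st <- synthesize_population(params, 1e6, seed = 5)
  t1 <- simulate_horizon(st, baseline_scenario(), params, years = 3)
  t2 <- simulate_horizon(st, baseline_scenario(), params, years = 3)
  expect_identical(t1$flows, t2$flows)
  expect_identical(tibble::as_tibble(t1$final_state),
                   tibble::as_tibble(t2$final_state))

  # a scenario with zero uptake produces the baseline trajectory
  null_sc <- builtin_scenarios()$targeted
  null_sc$hhc_uptake_by_age[] <- 0
  t3 <- simulate_horizon(st, null_sc, params, years = 3)
  expect_equal(t3$flows$ace_incident, t1$flows$ace_incident, tolerance = 1e-12)
  expect_equal(t3$flows$ace_deaths, t1$flows$ace_deaths, tolerance = 1e-12)
  expect_equal(sum(t3$flows$prs_tests), 0)
})

test_that("a one-cell closed cohort matches an independent yearly ledger", {
  params <- closed_demography(default_params_fixture(), mortality = 0.01)
  # 75+ band: no ageing, so the cohort stays in one cell
  id <- find_cell(sex = "male", age_band = "75+", tc_level = "tc_mid",
                  hdl_level = "hdl_low", sbp_level = "sbp_2",
                  tc_treated = FALSE, sbp_treated = FALSE,
                  diabetes = "ngr", smoking = "never")
  m <- params$demography$non_ace_mortality
  m$prob <- ifelse(m$sex == "male" & m$age_band == "75+", 0.05, 0)
  params$demography$non_ace_mortality <- m

  st <- toy_state(id, primary = 10000)
  traj <- simulate_horizon(st, baseline_scenario(), params, years = 10)

  risks <- cell_risks(cad_cells(), params)
  p <- risks$p_annual[id]
  ps <- risks$p_secondary[id]
  e <- params$events
  r_ann <- 1 - sqrt(1 - e$two_year_recurrence)
  q <- 0.05
  mult <- e$high_risk_multipliers[["male_non_ohca"]]
  mult_o <- e$high_risk_multipliers[["ohca_any_sex"]]

  # independent scalar ledger following the documented step order
  pool <- 10000; y1o <- 0; y1n <- 0; y2o <- 0; y2n <- 0; chd <- 0
  led_cases <- led_deaths <- numeric(10)
  for (y in 1:10) {
    inc <- pool * p
    rec <- (y1o + y1n + y2o + y2n) * r_ann + chd * ps
    events <- inc + rec
    ohca <- events * e$ohca_fraction
    ohca_d <- ohca * (1 - e$ohca_initial_survival)
    hosp <- events - ohca
    hosp_d <- hosp * e$thirty_day_mortality
    pool <- pool - inc
    y1o_s <- y1o * (1 - r_ann); y1n_s <- y1n * (1 - r_ann)
    y2o_s <- y2o * (1 - r_ann); y2n_s <- y2n * (1 - r_ann)
    chd <- chd * (1 - ps)
    ex <- function(s, m_) s * pmax(pmin(1, m_ * q) - q, 0)
    excess <- ex(y1o_s, mult_o) + ex(y2o_s, mult_o) +
      ex(y1n_s, mult) + ex(y2n_s, mult)
    y1o_s <- y1o_s - ex(y1o_s, mult_o); y1n_s <- y1n_s - ex(y1n_s, mult)
    y2o_s <- y2o_s - ex(y2o_s, mult_o); y2n_s <- y2n_s - ex(y2n_s, mult)
    chd <- chd + y2o_s + y2n_s
    y2o <- y1o_s; y2n <- y1n_s
    y1o <- ohca - ohca_d; y1n <- hosp - hosp_d
    # base mortality on every compartment
    pool <- pool * (1 - q); chd <- chd * (1 - q)
    y1o <- y1o * (1 - q); y1n <- y1n * (1 - q)
    y2o <- y2o * (1 - q); y2n <- y2n * (1 - q)
    led_cases[y] <- events
    led_deaths[y] <- ohca_d + hosp_d + excess
  }
  expect_equal(traj$yearly$ace_cases, led_cases, tolerance = 1e-9)
  expect_equal(traj$yearly$ace_deaths, led_deaths, tolerance = 1e-9)
  expect_equal(traj$yearly$persons_end[10],
               pool + y1o + y1n + y2o + y2n + chd, tolerance = 1e-9)
})

test_that("persons are conserved every simulated year", {
  params <- default_params_fixture()
  st <- synthesize_population(params, 2e6, seed = 9)
  for (sc in list(baseline_scenario(), builtin_scenarios()$maximal)) {
    traj <- simulate_horizon(st, sc, params, years = 5)
    yr <- traj$yearly
    expect_equal(
      yr$persons_end,
      yr$persons_start + yr$inflow + yr$net_migration -
        yr$ace_deaths - yr$non_ace_deaths,
      tolerance = 1e-6
    )
  }
})

test_that("no compartment goes negative across a parameter sweep", {
  params <- default_params_fixture()
  params$events$ohca_fraction <- 0.9
  params$events$thirty_day_mortality <- 0.95
  params$events$two_year_recurrence <- 0.9
  params$risk$secondary_multiplier <- 10
  st <- synthesize_population(params, 1e6, seed = 3)
  traj <- simulate_horizon(st, builtin_scenarios()$maximal, params, years = 4)
  fin <- tibble::as_tibble(traj$final_state)
  for (cc in cadprs:::COMPARTMENTS) expect_true(all(fin[[cc]] >= 0))
  expect_true(all(fin$tested_prs >= 0 & fin$on_statin >= 0))
})

test_that("trajectory flows serialize to tidy CSV", {
  params <- default_params_fixture()
  st <- synthesize_population(params, 1e5, seed = 1)
  traj <- simulate_horizon(st, builtin_scenarios()$targeted, params, years = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f)
  back <- utils::read.csv(f)
  expect_setequal(unique(back$flow),
                  c("ace_incident", "ace_recurrent", "ohca_events",
                    "ace_deaths", "non_ace_deaths", "prs_tests", "hhc_visits",
                    "statin_person_years", "prior_chd_person_years"))
  expect_equal(sum(back$value[back$flow == "ace_deaths"]),
               sum(traj$flows$ace_deaths), tolerance = 1e-9)
})
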