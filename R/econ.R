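ECON_MEASURES <- c("healthcare_costs", "prs_cost", "net_cost", "qalys_gained",
                   "value_of_qalys", "cost_per_qaly", "net_benefit",
                   "ace_deaths_averted", "ace_cases_averted")

traj_flows <- function(trajectory, sexes = c("male", "female")) {
  dplyr::filter(trajectory$flows, .data$sex %in% sexes)
}

discount_factors <- function(years, rate) 1 / (1 + rate)^(years - 1)

#' Total ACE-related healthcare costs of a trajectory (AU$m)
#'
#' Sum over years of acute event costs (every incident or recurrent event
#' times the acute unit cost, covering ambulance, hospital and
#' rehabilitation), chronic prior-CHD care (person-years times the annual
#' chronic cost) and statin therapy (covered person-years times the annual
#' statin cost). Undiscounted by default.
#'
#' @param trajectory A `cad_trajectory`.
#' @param costs Cost block ([default_cost_params()]).
#' @param discount_rate Annual discount rate (default 0).
#' @param sexes Restrict to one sex for subgroup results.
#' @return Cost in AU$ millions.
#' @export
healthcare_costs <- function(trajectory, costs = default_cost_params(),
                             discount_rate = 0,
                             sexes = c("male", "female")) {
  fl <- traj_flows(trajectory, sexes)
  df <- discount_factors(fl$year, discount_rate)
  sum(df * ((fl$ace_incident + fl$ace_recurrent) * costs$ace_acute_cost +
              fl$prior_chd_person_years * costs$chronic_annual_cost +
              fl$statin_person_years * costs$statin_cost_per_year)) / 1e6
}

#' Cost of PRS tests performed (AU$m)
#'
#' @param tests Number of tests.
#' @param unit Unit cost (default A$147.20, US$100 at a fixed conversion).
#' @return Cost in AU$ millions.
#' @export
prs_cost <- function(tests, unit = 147.20) {
  stopifnot(all(tests >= 0))
  tests * unit / 1e6
}

#' Net cost of a scenario relative to baseline (AU$m)
#'
#' Excess healthcare expenditure above baseline (statin therapy included in
#' the scenario's healthcare costs, savings from averted events netted out)
#' plus the cost of the PRS tests themselves.
#'
#' @param scenario_costs,baseline_costs Healthcare costs (AU$m).
#' @param prs_cost PRS testing cost (AU$m).
#' @return Net cost in AU$ millions.
#' @export
net_cost <- function(scenario_costs, baseline_costs, prs_cost) {
  scenario_costs - baseline_costs + prs_cost
}

averted_by_stratum <- function(baseline_traj, scenario_traj, sexes) {
  agg <- function(traj) {
    dplyr::summarise(
      dplyr::group_by(traj_flows(traj, sexes), .data$sex, .data$age_band,
                      .data$year),
      cases = sum(.data$ace_incident + .data$ace_recurrent),
      deaths = sum(.data$ace_deaths),
      chd_py = sum(.data$prior_chd_person_years),
      .groups = "drop"
    )
  }
  dplyr::full_join(agg(baseline_traj), agg(scenario_traj),
                   by = c("sex", "age_band", "year"),
                   suffix = c("_b", "_s"))
}

#' QALYs gained by a scenario relative to baseline
#'
#' Three-term valuation: averted ACE deaths times the remaining
#' quality-adjusted life expectancy (QALE) at the age/sex of death, plus
#' averted non-fatal events times the per-event utility decrement, plus
#' averted prior-CHD person-years times the chronic annual decrement.
#'
#' @param baseline_traj,scenario_traj Matched `cad_trajectory` objects
#'   (same population, horizon).
#' @param utilities Utility block ([default_utility_params()]).
#' @param sexes Restrict to one sex for subgroup results.
#' @return QALYs gained (scalar).
#' @export
qalys_gained <- function(baseline_traj, scenario_traj,
                         utilities = default_utility_params(),
                         sexes = c("male", "female")) {
  if (any(utilities$qale$qale < 0)) stop("QALE must be >= 0", call. = FALSE)
  av <- averted_by_stratum(baseline_traj, scenario_traj, sexes)
  qale <- utilities$qale$qale[match(paste(av$sex, av$age_band),
                                    paste(utilities$qale$sex,
                                          utilities$qale$age_band))]
  df <- discount_factors(av$year, utilities$discount_rate)
  deaths_av <- av$deaths_b - av$deaths_s
  cases_av <- av$cases_b - av$cases_s
  chd_av <- av$chd_py_b - av$chd_py_s
  sum(df * (deaths_av * qale +
              (cases_av - deaths_av) * utilities$event_utility_decrement +
              chd_av * utilities$chronic_utility_decrement))
}

#' Monetary value of QALYs gained (AU$m)
#' @param qalys QALYs gained.
#' @param wtp Willingness to pay per QALY (default A$50,000).
#' @return Value in AU$ millions.
#' @export
value_of_qalys <- function(qalys, wtp = 50000) qalys * wtp / 1e6

#' Net cost per QALY gained (AU$)
#'
#' @param net_cost Net cost (AU$m).
#' @param qalys QALYs gained; if not positive the ratio is undefined and
#'   `NA` is returned (inert or dominated scenario).
#' @return AU$ per QALY.
#' @export
cost_per_qaly <- function(net_cost, qalys) {
  ifelse(qalys > 0, net_cost * 1e6 / qalys, NA_real_)
}

#' Net monetary benefit (AU$m)
#'
#' Value of QALYs gained minus net cost.
#'
#' @param value_of_qalys,net_cost AU$m.
#' @return AU$m.
#' @export
net_benefit <- function(value_of_qalys, net_cost) value_of_qalys - net_cost

# the nine headline measures for one scenario run vs baseline, one sex
# subset; returns tibble(measure, value)
econ_measures <- function(baseline_traj, scenario_traj, params,
                          sexes = c("male", "female")) {
  costs <- params$costs
  hc_b <- healthcare_costs(baseline_traj, costs, sexes = sexes)
  hc_s <- healthcare_costs(scenario_traj, costs, sexes = sexes)
  tests <- sum(traj_flows(scenario_traj, sexes)$prs_tests)
  pc <- prs_cost(tests, costs$prs_unit_cost)
  nc <- net_cost(hc_s, hc_b, pc)
  q <- qalys_gained(baseline_traj, scenario_traj, params$utilities, sexes)
  vq <- value_of_qalys(q, costs$wtp_per_qaly)
  fb <- traj_flows(baseline_traj, sexes)
  fs <- traj_flows(scenario_traj, sexes)
  deaths_av <- sum(fb$ace_deaths) - sum(fs$ace_deaths)
  cases_av <- sum(fb$ace_incident + fb$ace_recurrent) -
    sum(fs$ace_incident + fs$ace_recurrent)
  tibble::tibble(
    measure = ECON_MEASURES,
    value = c(hc_s, pc, nc, q, vq, cost_per_qaly(nc, q), net_benefit(vq, nc),
              deaths_av, cases_av)
  )
}

#' Evaluate a scenario's health-economic outcomes against baseline
#'
#' Simulates the baseline (no screening) and the scenario on the same
#' initial population, overall and per sex, at the point odds ratio and at
#' both ends of its confidence bracket, and assembles the nine headline
#' measures (healthcare costs, PRS cost, net cost, QALYs gained, value of
#' QALYs, cost per QALY, net benefit, ACE deaths and cases averted), each
#' with `[low, high]` bounds from the odds-ratio sweep.
#'
#' @param state0 Initial `cad_population`.
#' @param scenario A `cad_scenario`.
#' @param params A `cad_params` object.
#' @param years Horizon (default 10).
#' @param odds_ratio Point odds ratio (default from `params`).
#' @param or_ci Bracket, e.g. `c(1.8, 2.0)`; set equal to the point value
#'   to skip the sweep.
#' @param baseline_traj Optional precomputed baseline trajectory (reused
#'   across scenarios; must share `state0`, `params`, `years`).
#' @return A `cad_econ` object; see [tidy.cad_econ()], [glance.cad_econ()],
#'   [autoplot.cad_econ()].
#' @export
evaluate_scenario <- function(state0, scenario, params = default_parameters(),
                              years = 10,
                              odds_ratio = params$risk$prs_odds_ratio,
                              or_ci = params$risk$prs_or_ci,
                              baseline_traj = NULL) {
  if (is.null(baseline_traj)) {
    baseline_traj <- simulate_horizon(state0, baseline_scenario(), params,
                                      years, odds_ratio = odds_ratio)
  }
  run_at <- function(or) {
    traj <- simulate_horizon(state0, scenario, params, years, odds_ratio = or)
    dplyr::bind_rows(
      dplyr::mutate(econ_measures(baseline_traj, traj, params), sex = "overall"),
      dplyr::mutate(econ_measures(baseline_traj, traj, params, "male"),
                    sex = "male"),
      dplyr::mutate(econ_measures(baseline_traj, traj, params, "female"),
                    sex = "female")
    )
  }
  point <- dplyr::rename(run_at(odds_ratio), estimate = "value")
  ors <- unique(c(or_ci, odds_ratio))
  bounds <- or_ci_bounds(run_at, ors)
  measures <- dplyr::left_join(point, bounds, by = c("measure", "sex"))

  baseline <- tibble::tibble(
    measure = c("healthcare_costs", "ace_deaths", "ace_cases"),
    value = c(healthcare_costs(baseline_traj, params$costs),
              sum(baseline_traj$yearly$ace_deaths),
              sum(baseline_traj$yearly$ace_cases))
  )
  structure(list(
    measures = measures,
    baseline = baseline,
    scenario = scenario$name,
    odds_ratio = odds_ratio,
    or_ci = or_ci,
    years = years,
    population = total_persons(state0),
    wtp_per_qaly = params$costs$wtp_per_qaly,
    baseline_traj = baseline_traj
  ), class = "cad_econ")
}

#' Odds-ratio sensitivity bracket for a set of measures
#'
#' Reruns the full pipeline at each odds ratio in the bracket and reports
#' the per-measure min/max as `[low, high]`.
#'
#' @param run_fn Function taking an odds ratio and returning a tibble with
#'   columns `measure`, `sex`, `value`.
#' @param odds_ratios Odds ratios to sweep (e.g. `c(1.8, 2.0)`).
#' @return Tibble `measure`, `sex`, `low`, `high`.
#' @export
or_ci_bounds <- function(run_fn, odds_ratios) {
  runs <- dplyr::bind_rows(lapply(odds_ratios, function(or) {
    dplyr::mutate(run_fn(or), or = or)
  }))
  dplyr::summarise(
    dplyr::group_by(runs, .data$measure, .data$sex),
    low = if (all(is.na(.data$value))) NA_real_ else
      min(.data$value, na.rm = TRUE),
    high = if (all(is.na(.data$value))) NA_real_ else
      max(.data$value, na.rm = TRUE),
    .groups = "drop"
  )
}

#' @export
print.cad_econ <- function(x, ...) {
  cat("<cad_econ> scenario:", x$scenario, " OR:", x$odds_ratio,
      sprintf("[%g-%g]", x$or_ci[1], x$or_ci[2]),
      " horizon:", x$years, "years\n")
  ov <- x$measures[x$measures$sex == "overall", ]
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %-20s %12.1f  [%.1f - %.1f]\n", ov$measure[i],
                ov$estimate[i], ov$low[i], ov$high[i]))
  }
  invisible(x)
}

#' Tidy the measures of a `cad_econ` result
#'
#' @param x A `cad_econ` object.
#' @param ... Unused.
#' @return Tibble with columns `scenario`, `measure`, `sex`, `estimate`,
#'   `low`, `high` (bounds from the odds-ratio bracket).
#' @export
tidy.cad_econ <- function(x, ...) {
  dplyr::mutate(
    dplyr::select(x$measures, "measure", "sex", "estimate", "low", "high"),
    scenario = x$scenario, .before = 1
  )
}

#' One-row summary of a `cad_econ` result
#'
#' @param x A `cad_econ` object.
#' @param ... Unused.
#' @return One-row tibble: scenario, odds ratio, QALYs gained, net cost,
#'   cost per QALY, net benefit, deaths/cases averted, and whether the cost
#'   per QALY stays below the willingness-to-pay threshold across the whole
#'   odds-ratio bracket.
#' @export
glance.cad_econ <- function(x, ...) {
  ov <- x$measures[x$measures$sex == "overall", ]
  g <- function(m, col = "estimate") ov[[col]][ov$measure == m]
  tibble::tibble(
    scenario = x$scenario,
    odds_ratio = x$odds_ratio,
    qalys_gained = g("qalys_gained"),
    net_cost = g("net_cost"),
    cost_per_qaly = g("cost_per_qaly"),
    net_benefit = g("net_benefit"),
    ace_deaths_averted = g("ace_deaths_averted"),
    ace_cases_averted = g("ace_cases_averted"),
    below_wtp = g("cost_per_qaly", "high") < x$wtp_per_qaly
  )
}

#' Cost-effectiveness plot of one or more scenario evaluations
#'
#' Cost per QALY gained versus QALYs gained (thousands), overall and by
#' sex, with the odds-ratio bracket as crossbars and the willingness-to-pay
#' threshold as a horizontal line.
#'
#' @param object A `cad_econ` object, or a list of them.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cad_econ <- function(object, ...) {
  objs <- if (inherits(object, "cad_econ")) list(object) else object
  dat <- dplyr::bind_rows(lapply(objs, function(x) {
    m <- x$measures
    wide <- tibble::tibble(
      scenario = x$scenario,
      sex = unique(m$sex),
      qalys = m$estimate[m$measure == "qalys_gained"],
      qalys_low = m$low[m$measure == "qalys_gained"],
      qalys_high = m$high[m$measure == "qalys_gained"],
      cpq = m$estimate[m$measure == "cost_per_qaly"],
      cpq_low = m$low[m$measure == "cost_per_qaly"],
      cpq_high = m$high[m$measure == "cost_per_qaly"]
    )
    wide
  }))
  wtp <- objs[[1]]$wtp_per_qaly
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$qalys / 1e3, y = .data$cpq,
                                    colour = .data$sex,
                                    shape = .data$scenario)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$cpq_low,
                                        ymax = .data$cpq_high), width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$qalys_low / 1e3,
                                         xmax = .data$qalys_high / 1e3),
                            height = 0) +
    ggplot2::geom_hline(yintercept = wtp, linetype = "dashed") +
    ggplot2::labs(x = "QALYs gained (thousands)",
                  y = "Cost per QALY gained (AU$)",
                  colour = "Group", shape = "Scenario") +
    ggplot2::theme_minimal()
}
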