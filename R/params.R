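#' Default model parameters
#'
#' Bundles every parameter block of the model: demography (synthetic
#' stand-ins for national survey data), the risk engine, acute-event
#' parameters, costs and utilities. All values are configurable; the
#' defaults are documented in the methods vignette. Blocks can be replaced
#' wholesale or field-by-field via `modifyList()` semantics.
#'
#' @param ... Named blocks or fields overriding the defaults, e.g.
#'   `events = list(ohca_fraction = 0.15)`.
#' @return A list of class `cad_params` with blocks `demography`,
#'   `risk`, `events`, `costs`, `utilities`, `rep_values`.
#' @export
default_parameters <- function(...) {
  params <- structure(list(
    demography = default_demography(),
    risk = default_risk_params(),
    events = default_event_params(),
    costs = default_cost_params(),
    utilities = default_utility_params(),
    rep_values = default_representative_values()
  ), class = "cad_params")
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(params[[nm]]) && is.list(overrides[[nm]])) {
      params[[nm]] <- utils::modifyList(params[[nm]], overrides[[nm]])
    } else {
      params[[nm]] <- overrides[[nm]]
    }
  }
  validate_parameters(params)
  params
}

band_tbl <- function(male, female, value_name) {
  bands <- cell_levels()$age_band
  tibble::tibble(
    sex = rep(c("male", "female"), each = length(bands)),
    age_band = rep(bands, 2),
    "{value_name}" := c(male, female)
  )
}

#' Synthetic demography defaults
#'
#' Age/sex structure, risk-factor prevalence margins, non-ACE mortality,
#' inflow and net migration for a synthetic high-income adult population of
#' about 20 million. These are plausible stand-ins, not fitted values; see
#' the methods vignette.
#'
#' @return A list with elements `age_sex_margins`, `factor_margins`,
#'   `non_ace_mortality`, `inflow_by_sex`, `net_migration`,
#'   `prior_chd_seed`, `total_persons`.
#' @export
default_demography <- function() {
  bands <- cell_levels()$age_band
  age_share <- c(0.27, 0.175, 0.17, 0.155, 0.125, 0.105)
  male_share <- 0.494
  age_sex <- tibble::tibble(
    sex = rep(c("male", "female"), each = 6),
    age_band = rep(bands, 2),
    prob = c(age_share * male_share, age_share * (1 - male_share))
  )

  # prevalence margins per factor, by age band (sex-specific where it
  # matters); probabilities within a factor sum to 1 in each stratum
  m <- function(factor, level, male, female = male) {
    tibble::tibble(
      factor = factor,
      level = as.character(level),
      sex = rep(c("male", "female"), each = 6),
      age_band = rep(bands, 2),
      prob = c(male, female)
    )
  }
  factor_margins <- dplyr::bind_rows(
    m("tc_level", "tc_low",  c(.70, .60, .50, .45, .45, .50)),
    m("tc_level", "tc_mid",  c(.25, .30, .35, .35, .35, .35)),
    m("tc_level", "tc_high", c(.05, .10, .15, .20, .20, .15)),
    m("tc_treated", "TRUE",  c(.01, .05, .15, .30, .45, .50)),
    m("tc_treated", "FALSE", 1 - c(.01, .05, .15, .30, .45, .50)),
    m("hdl_level", "hdl_low",  rep(.35, 6), rep(.20, 6)),
    m("hdl_level", "hdl_high", rep(.65, 6), rep(.80, 6)),
    m("sbp_level", "sbp_1", c(.60, .50, .40, .30, .22, .18)),
    m("sbp_level", "sbp_2", c(.30, .33, .35, .35, .34, .30)),
    m("sbp_level", "sbp_3", c(.08, .13, .18, .24, .28, .30)),
    m("sbp_level", "sbp_4", c(.02, .04, .07, .11, .16, .22)),
    m("sbp_treated", "TRUE",  c(.02, .08, .20, .35, .50, .60)),
    m("sbp_treated", "FALSE", 1 - c(.02, .08, .20, .35, .50, .60)),
    m("diabetes", "ngr",  c(.95, .90, .85, .78, .72, .70)),
    m("diabetes", "igt",  c(.04, .07, .09, .12, .14, .14)),
    m("diabetes", "t2dm", c(.01, .03, .06, .10, .14, .16)),
    m("smoking", "never",   c(.55, .50, .45, .42, .40, .45),
                            c(.60, .55, .50, .47, .45, .50)),
    m("smoking", "ex",      c(.15, .22, .30, .38, .47, .48)),
    m("smoking", "current", c(.30, .28, .25, .20, .13, .07),
                            c(.25, .23, .20, .15, .08, .02))
  )

  list(
    age_sex_margins = age_sex,
    factor_margins = factor_margins,
    non_ace_mortality = band_tbl(
      c(.0008, .0015, .0030, .0060, .0150, .080),
      c(.0004, .0008, .0018, .0040, .0100, .070),
      "prob"
    ),
    inflow_by_sex = c(male = 160000, female = 160000),  # persons/yr into 20-34
    net_migration = band_tbl(
      c(45000, 19000, 7500, 3500, 0, 0),
      c(45000, 19000, 7500, 3500, 0, 0),
      "persons"
    ),
    prior_chd_seed = c("20-34" = 0, "35-44" = 0.005, "45-54" = 0.02,
                       "55-64" = 0.05, "65-74" = 0.09, "75+" = 0.15),
    total_persons = 20.6e6
  )
}

#' Risk-engine defaults
#'
#' @return A list with the Framingham coefficient table (see
#'   [load_framingham_coefficients()]), an age-by-sex calibration multiplier
#'   table (all 1 by default), PRS odds ratio 1.9 with 95% CI bracket
#'   1.8-2.0, top-quintile fraction 0.20, the secondary-prevention
#'   recurrence multiplier, FRS banding thresholds (5-year risk 0.10 / 0.15)
#'   and the statin treatment model.
#' @export
default_risk_params <- function() {
  list(
    coefficients = load_framingham_coefficients(),
    calibration = band_tbl(rep(1, 6), rep(1, 6), "multiplier"),
    prs_odds_ratio = 1.9,
    prs_or_ci = c(1.8, 2.0),
    prs_top_fraction = 0.20,
    secondary_multiplier = 2.0,
    frs_thresholds = c(low = 0.10, medium = 0.15),
    treated_risk_mode = "set_to_low",   # or "rrr"
    statin_rrr = 0.47
  )
}

#' Acute-event defaults
#'
#' The high-risk mortality multipliers (1.425 men / 1.495 women without
#' out-of-hospital cardiac arrest, 3.9 with) and the 25% two-year
#' recurrence probability are literature values; the OHCA incidence,
#' initial survival and 30-day in-hospital mortality are synthetic
#' registry stand-ins.
#'
#' @return List of event parameters.
#' @export
default_event_params <- function() {
  list(
    ohca_fraction = 0.12,
    ohca_initial_survival = 0.30,
    thirty_day_mortality = 0.10,
    high_risk_multipliers = c(male_non_ohca = 1.425,
                              female_non_ohca = 1.495,
                              ohca_any_sex = 3.9),
    two_year_recurrence = 0.25,
    recurrent_events_split_ohca = TRUE
  )
}

#' Cost defaults (AU$)
#'
#' Statin therapy A$203.92/person-year and the PRS unit cost A$147.20
#' (US$100 at a fixed conversion) are published values; the acute-event and
#' chronic care costs are synthetic, scaled so the baseline run's cost per
#' case has the reported tens-of-thousands magnitude.
#'
#' @return List of unit costs and the A$50,000/QALY willingness-to-pay.
#' @export
default_cost_params <- function() {
  list(
    statin_cost_per_year = 203.92,
    prs_unit_cost = 147.20,
    ace_acute_cost = 28000,
    chronic_annual_cost = 1800,
    wtp_per_qaly = 50000
  )
}

#' Utility (QALY) defaults
#'
#' Remaining quality-adjusted life expectancy (QALE) by age band and sex
#' values an averted death; decrements value averted non-fatal events and
#' averted chronic-disease person-years. Discounting defaults to 0.
#'
#' @return List with `qale`, `event_utility_decrement`,
#'   `chronic_utility_decrement`, `discount_rate`.
#' @export
default_utility_params <- function() {
  list(
    qale = band_tbl(c(45, 36, 28, 20, 13, 7),
                    c(48, 39, 30, 22, 15, 8), "qale"),
    event_utility_decrement = 0.08,
    chronic_utility_decrement = 0.06,
    discount_rate = 0
  )
}

#' Validate a `cad_params` object
#'
#' Checks probability ranges, margin normalisation (each factor's levels
#' sum to 1 within every age-by-sex stratum), multiplier bounds and cost
#' signs. Called by [default_parameters()]; call directly after manual
#' edits.
#'
#' @param params A `cad_params` list.
#' @return `params`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_parameters <- function(params) {
  d <- params$demography
  chk_prob <- function(x, what) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      stop(what, " must be probabilities in [0, 1]", call. = FALSE)
    }
  }
  chk_prob(d$age_sex_margins$prob, "demography$age_sex_margins$prob")
  if (abs(sum(d$age_sex_margins$prob) - 1) > 1e-8) {
    stop("demography$age_sex_margins must sum to 1", call. = FALSE)
  }
  if (any(d$factor_margins$prob < 0)) {
    bad <- unique(d$factor_margins$factor[d$factor_margins$prob < 0])
    stop("negative prevalence margin for factor: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sums <- dplyr::summarise(
    dplyr::group_by(d$factor_margins, .data$factor, .data$sex, .data$age_band),
    s = sum(.data$prob), .groups = "drop"
  )
  off <- sums[abs(sums$s - 1) > 1e-8, ]
  if (nrow(off) > 0) {
    stop("prevalence margins do not sum to 1 for factor: ",
         paste(unique(off$factor), collapse = ", "), call. = FALSE)
  }
  chk_prob(d$non_ace_mortality$prob, "demography$non_ace_mortality$prob")
  chk_prob(d$prior_chd_seed, "demography$prior_chd_seed")

  r <- params$risk
  if (r$prs_odds_ratio <= 0) stop("prs_odds_ratio must be > 0", call. = FALSE)
  if (r$prs_top_fraction <= 0 || r$prs_top_fraction >= 1) {
    stop("prs_top_fraction must be in (0, 1)", call. = FALSE)
  }
  if (any(r$calibration$multiplier <= 0)) {
    stop("calibration multipliers must be > 0", call. = FALSE)
  }
  if (r$secondary_multiplier < 1) {
    stop("secondary_multiplier must be >= 1", call. = FALSE)
  }

  e <- params$events
  chk_prob(c(e$ohca_fraction, e$ohca_initial_survival,
             e$thirty_day_mortality, e$two_year_recurrence),
           "event probabilities")
  if (any(e$high_risk_multipliers < 1)) {
    stop("high_risk_multipliers must be >= 1", call. = FALSE)
  }

  if (any(unlist(params$costs) < 0)) {
    stop("costs must be >= 0", call. = FALSE)
  }
  u <- params$utilities
  if (any(u$qale$qale < 0) || u$event_utility_decrement < 0 ||
      u$chronic_utility_decrement < 0) {
    stop("utility decrements and QALE must be >= 0", call. = FALSE)
  }
  invisible(params)
}
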