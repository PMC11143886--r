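#' Load the Framingham 2008 general-CVD coefficient table
#'
#' Reads the sex-specific Cox-model coefficients of the published 2008
#' general cardiovascular disease risk function (log-transformed
#' covariates), together with each sex's 10-year baseline survival and the
#' aggregate mean linear predictor, from a CSV fixture. The schema is
#' validated on load: columns `sex`, `term`, `beta`, `mean`; covariate
#' terms `ln_age`, `ln_tc`, `ln_hdl`, `ln_sbp_untreated`,
#' `ln_sbp_treated`, `smoker`, `diabetes`; bookkeeping rows `mean_lp` and
#' `baseline_survival_10y` per sex.
#'
#' @param path CSV file; defaults to the fixture shipped with the package.
#' @return A tibble of coefficients with attribute `horizon_years = 10`.
#' @export
load_framingham_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "framingham_2008_coefficients.csv",
                        package = "cadprs", mustWork = TRUE)
  }
  coef <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  required_terms <- c("ln_age", "ln_tc", "ln_hdl", "ln_sbp_untreated",
                      "ln_sbp_treated", "smoker", "diabetes", "mean_lp",
                      "baseline_survival_10y")
  if (!all(c("sex", "term", "beta") %in% names(coef))) {
    stop("coefficient fixture must have columns sex, term, beta", call. = FALSE)
  }
  for (s in c("male", "female")) {
    have <- coef$term[coef$sex == s]
    missing <- setdiff(required_terms, have)
    if (length(missing) > 0) {
      stop("coefficient fixture missing terms for ", s, ": ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(coef, horizon_years = 10)
}

coef_lookup <- function(coefficients, sex, term) {
  v <- coefficients$beta[coefficients$sex == sex & coefficients$term == term]
  if (length(v) != 1 || !is.finite(v)) {
    stop("missing coefficient '", term, "' for sex '", sex, "'", call. = FALSE)
  }
  v
}

#' Framingham general-CVD risk over a 5- or 10-year horizon
#'
#' Computes `1 - S0(t)^exp(LP - meanLP)` from the published sex-specific
#' model, where the linear predictor LP uses log age, log total
#' cholesterol, log HDL, log SBP (with separate coefficients by
#' antihypertensive treatment), smoking and diabetes indicators. The
#' 10-year horizon is native to the coefficient table; the 5-year risk is
#' obtained by constant-hazard scaling of the 10-year risk
#' (`1 - (1 - p10)^(1/2)`), recorded in the result's
#' `"horizon_method"` attribute.
#'
#' All arguments are vectorised over profiles; pass a data frame via
#' [cell_profiles()] for per-cell risks.
#'
#' @param profiles Data frame with columns `sex`, `age_years`, `tc`, `hdl`
#'   (mg/dL), `sbp` (mmHg), `sbp_rx`, `diabetic`, `smoker`.
#' @param params Risk-engine parameter block ([default_risk_params()]).
#' @param horizon_years 5 or 10.
#' @return Numeric vector of risks in `[0, 1]`, one per profile row.
#' @export
framingham_risk <- function(profiles, params = default_risk_params(),
                            horizon_years = 10) {
  if (!horizon_years %in% c(5, 10)) {
    stop("horizon_years must be 5 or 10", call. = FALSE)
  }
  coefs <- params$coefficients
  sex <- as.character(profiles$sex)
  if (!all(sex %in% c("male", "female"))) {
    stop("unknown sex level in profiles", call. = FALSE)
  }
  b <- function(term) {
    vapply(c("male", "female"), function(s) coef_lookup(coefs, s, term),
           numeric(1))[sex]
  }
  lp <- b("ln_age") * log(profiles$age_years) +
    b("ln_tc") * log(profiles$tc) +
    b("ln_hdl") * log(profiles$hdl) +
    ifelse(profiles$sbp_rx, b("ln_sbp_treated"), b("ln_sbp_untreated")) *
      log(profiles$sbp) +
    b("smoker") * as.numeric(profiles$smoker) +
    b("diabetes") * as.numeric(profiles$diabetic)
  s0 <- b("baseline_survival_10y")
  p10 <- 1 - s0^exp(lp - b("mean_lp"))
  p10 <- pmin(pmax(p10, 0), 1)
  if (horizon_years == 10) {
    structure(p10, horizon_method = "native_10y")
  } else {
    structure(1 - (1 - p10)^(5 / 10), horizon_method = "hazard_scaled_from_10y")
  }
}

#' Convert a multi-year risk to an annual probability
#'
#' Constant-hazard (exponential) conversion:
#' `1 - (1 - p)^(1/horizon)`.
#'
#' @param p Probability over the horizon, in `[0, 1)`.
#' @param horizon_years Horizon length in years, >= 1.
#' @return Annual probability.
#' @examples
#' annualize(0.10, 10) # ~0.01048
#' @export
annualize <- function(p, horizon_years) {
  if (any(p < 0 | p >= 1)) {
    stop("p must be in [0, 1): p = 1 implies an infinite hazard", call. = FALSE)
  }
  if (any(horizon_years < 1)) stop("horizon_years must be >= 1", call. = FALSE)
  1 - (1 - p)^(1 / horizon_years)
}

#' Band a 5-year Framingham risk into low / medium / high
#'
#' Boundaries are inclusive: risk <= the low threshold is `low`, risk <=
#' the medium threshold is `medium`, above that `high`. PRS eligibility in
#' the targeted and intermediate scenarios requires `low` or `medium`
#' (5-year FRS <= 15%); the low-risk programme variant uses <= 10%.
#'
#' @param p5 5-year risk, vectorised.
#' @param thresholds Named vector `c(low = 0.10, medium = 0.15)`.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
frs_band <- function(p5, thresholds = c(low = 0.10, medium = 0.15)) {
  stopifnot(all(p5 >= 0 & p5 <= 1), thresholds["low"] <= thresholds["medium"])
  factor(
    ifelse(p5 <= thresholds[["low"]], "low",
           ifelse(p5 <= thresholds[["medium"]], "medium", "high")),
    levels = c("low", "medium", "high")
  )
}

#' Per-cell annual risks and FRS bands for the whole stratification
#'
#' Computes, for every risk cell: the 10-year Framingham risk, the 5-year
#' risk, the calibrated 1-year primary-prevention ACE probability
#' (constant-hazard annualisation of the 10-year risk, times the
#' age-by-sex calibration multiplier), its PRS decomposition into
#' top-quintile and remainder risks, the treated top-quintile risk, the
#' secondary-prevention (prior-CHD) annual risk, and the FRS band.
#'
#' @param cells Cell table from [cad_cells()].
#' @param params Full `cad_params` object.
#' @param odds_ratio PRS odds ratio override (defaults to the parameter
#'   block's value); used for the confidence-interval bracket.
#' @return `cells` plus columns `p10`, `p5`, `p_annual`, `p_high`, `p_low`,
#'   `p_high_treated`, `p_secondary`, `frs_band`.
#' @export
cell_risks <- function(cells, params = default_parameters(),
                       odds_ratio = params$risk$prs_odds_ratio) {
  prof <- cell_profiles(cells, params$rep_values)
  p10 <- framingham_risk(prof, params$risk, 10)
  p5 <- framingham_risk(prof, params$risk, 5)
  cal <- dplyr::left_join(
    dplyr::mutate(cells, sex = as.character(.data$sex),
                  age_band = as.character(.data$age_band)),
    params$risk$calibration, by = c("sex", "age_band")
  )$multiplier
  p_annual <- pmin(annualize(pmin(as.numeric(p10), 1 - 1e-12), 10) * cal,
                   1 - 1e-12)
  dec <- decompose_by_prs(p_annual, odds_ratio, params$risk$prs_top_fraction)
  treated <- treated_high_prs_risk(dec$p_high, dec$p_low,
                                   mode = params$risk$treated_risk_mode,
                                   rrr = params$risk$statin_rrr)
  dplyr::mutate(
    cells,
    p10 = as.numeric(p10),
    p5 = as.numeric(p5),
    p_annual = p_annual,
    p_high = dec$p_high,
    p_low = dec$p_low,
    p_high_treated = treated,
    p_secondary = pmin(p_annual * params$risk$secondary_multiplier, 1),
    frs_band = frs_band(.data$p5, params$risk$frs_thresholds)
  )
}

#' Calibrate modelled event counts to observed counts
#'
#' Per age-by-sex stratum multiplier = observed / modelled. Strata with
#' zero modelled events are flagged with a warning and left at 1.
#'
#' @param observed,modeled Data frames with columns `sex`, `age_band`,
#'   `events`.
#' @return A calibration table (`sex`, `age_band`, `multiplier`) suitable
#'   for `params$risk$calibration`.
#' @export
calibrate <- function(observed, modeled) {
  stopifnot(all(c("sex", "age_band", "events") %in% names(observed)),
            all(c("sex", "age_band", "events") %in% names(modeled)))
  tab <- dplyr::left_join(
    dplyr::rename(observed, obs = "events"),
    dplyr::rename(modeled, mod = "events"),
    by = c("sex", "age_band")
  )
  if (anyNA(tab$mod)) stop("modeled events missing for some strata", call. = FALSE)
  zero <- tab$mod <= 0
  if (any(zero)) {
    warning(sum(zero), " strata have zero modelled events; multiplier left at 1")
  }
  dplyr::transmute(
    tab, sex = .data$sex, age_band = .data$age_band,
    multiplier = ifelse(zero, 1, .data$obs / .data$mod)
  )
}
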