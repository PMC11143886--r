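#' Default statin adherence table (synthetic placeholder)
#'
#' Fraction of the prescribed stock effectively covered in a year, by age
#' band and sex. The survey-derived table the model design calls for is not
#' public; these defaults are synthetic, monotone in age and lower in
#' younger men, and flagged as placeholders in the methods vignette.
#'
#' @return Tibble with columns `sex`, `age_band`, `adherence`.
#' @export
default_adherence_table <- function() {
  band_tbl(c(0.50, 0.50, 0.55, 0.65, 0.75, 0.80),
           c(0.55, 0.55, 0.60, 0.70, 0.80, 0.85), "adherence")
}

#' Default annual statin discontinuation table (synthetic placeholder)
#' @return Tibble with columns `sex`, `age_band`, `discontinuation`.
#' @export
default_discontinuation_table <- function() {
  band_tbl(rep(0.05, 6), rep(0.05, 6), "discontinuation")
}

#' Construct a screening/intervention scenario
#'
#' Encodes who is offered a polygenic risk score and what happens next:
#' the eligible age range, whether testing requires attending a Heart
#' Health Check (HHC) and its per-age uptake, the 5-year FRS eligibility
#' ceiling (testing is restricted to low-to-medium traditional risk unless
#' `everyone_eligible` is set), the PRS referral rate among eligible
#' attenders, the statin prescription rate among high-PRS results, and
#' adherence/discontinuation behaviour.
#'
#' @param name Scenario label.
#' @param prs_age_min,prs_age_max PRS-eligible age range in years
#'   (mapped to whole age bands).
#' @param requires_hhc Does testing require a HHC visit?
#' @param hhc_uptake_by_age Named vector of annual HHC attendance
#'   probabilities by age band (bands outside the eligible range are
#'   ignored).
#' @param frs_eligibility_max 5-year FRS ceiling for PRS eligibility
#'   (0.15 default; 0.10 for the low-risk programme variant).
#' @param everyone_eligible If `TRUE`, FRS is not gated (maximal scenario).
#' @param prs_referral_rate Probability an eligible attender is referred.
#' @param statin_prescription_rate Probability a high-PRS result leads to a
#'   statin prescription.
#' @param adherence_table,discontinuation_table Age-by-sex tables; see
#'   [default_adherence_table()].
#' @param full_adherence If `TRUE`, adherence is 1 and discontinuation 0
#'   regardless of the tables (maximal scenario).
#' @return A list of class `cad_scenario`.
#' @export
scenario_config <- function(name,
                            prs_age_min, prs_age_max = Inf,
                            requires_hhc = TRUE,
                            hhc_uptake_by_age = NULL,
                            frs_eligibility_max = 0.15,
                            everyone_eligible = FALSE,
                            prs_referral_rate = 1,
                            statin_prescription_rate = 1,
                            adherence_table = default_adherence_table(),
                            discontinuation_table = default_discontinuation_table(),
                            full_adherence = FALSE) {
  bands <- cell_levels()$age_band
  if (is.null(hhc_uptake_by_age)) {
    hhc_uptake_by_age <- stats::setNames(rep(1, length(bands)), bands)
  }
  sc <- structure(list(
    name = name,
    prs_age_min = prs_age_min, prs_age_max = prs_age_max,
    requires_hhc = requires_hhc,
    hhc_uptake_by_age = hhc_uptake_by_age,
    frs_eligibility_max = frs_eligibility_max,
    everyone_eligible = everyone_eligible,
    prs_referral_rate = prs_referral_rate,
    statin_prescription_rate = statin_prescription_rate,
    adherence_table = adherence_table,
    discontinuation_table = discontinuation_table,
    full_adherence = full_adherence
  ), class = "cad_scenario")
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  rates <- c(sc$hhc_uptake_by_age, sc$prs_referral_rate,
             sc$statin_prescription_rate, sc$frs_eligibility_max,
             sc$adherence_table$adherence,
             sc$discontinuation_table$discontinuation)
  if (any(rates < 0 | rates > 1)) {
    stop("scenario rates must be in [0, 1]", call. = FALSE)
  }
  if (sc$prs_age_min > sc$prs_age_max) {
    stop("prs_age_min must not exceed prs_age_max", call. = FALSE)
  }
  invisible(sc)
}

# lower age bound of each band; a band is PRS-eligible when its lower
# bound lies inside [prs_age_min, prs_age_max]
band_lower_age <- function(age_band) {
  unname(c("20-34" = 20, "35-44" = 35, "45-54" = 45,
           "55-64" = 55, "65-74" = 65, "75+" = 75)[as.character(age_band)])
}

#' The three built-in implementation scenarios
#'
#' * `maximal`: everybody aged 35+ is PRS-tested regardless of traditional
#'   risk, all high-PRS (top quintile) individuals are prescribed a statin
#'   and adhere fully for the whole horizon.
#' * `intermediate`: everyone aged 45-74 attends a HHC; all with 5-year
#'   FRS <= 15% have a PRS; 75% of high-PRS results lead to a statin;
#'   graded adherence and discontinuation.
#' * `targeted`: HHC attendance 5%/year at 45-54 and 20%/year at 55+;
#'   PRS restricted to ages 45-74 with FRS <= 15%; 75% referral; 75%
#'   prescription; graded adherence and discontinuation.
#'
#' @return Named list of `cad_scenario` objects.
#' @export
builtin_scenarios <- function() {
  uniform <- function(p, bands_on) {
    bands <- cell_levels()$age_band
    stats::setNames(ifelse(bands %in% bands_on, p, 0), bands)
  }
  list(
    maximal = scenario_config(
      name = "maximal",
      prs_age_min = 35, prs_age_max = Inf,
      requires_hhc = FALSE,
      hhc_uptake_by_age = uniform(1, c("35-44", "45-54", "55-64", "65-74", "75+")),
      everyone_eligible = TRUE,
      prs_referral_rate = 1,
      statin_prescription_rate = 1,
      full_adherence = TRUE
    ),
    intermediate = scenario_config(
      name = "intermediate",
      prs_age_min = 45, prs_age_max = 74,
      requires_hhc = TRUE,
      hhc_uptake_by_age = uniform(1, c("45-54", "55-64", "65-74")),
      frs_eligibility_max = 0.15,
      prs_referral_rate = 1,
      statin_prescription_rate = 0.75
    ),
    targeted = scenario_config(
      name = "targeted",
      prs_age_min = 45, prs_age_max = 74,
      requires_hhc = TRUE,
      hhc_uptake_by_age = c("20-34" = 0, "35-44" = 0, "45-54" = 0.05,
                            "55-64" = 0.20, "65-74" = 0.20, "75+" = 0.20),
      frs_eligibility_max = 0.15,
      prs_referral_rate = 0.75,
      statin_prescription_rate = 0.75
    )
  )
}

#' A null scenario (no screening, no treatment): the baseline
#' @return A `cad_scenario` with zero uptake.
#' @export
baseline_scenario <- function() {
  bands <- cell_levels()$age_band
  scenario_config(
    name = "baseline",
    prs_age_min = 35,
    hhc_uptake_by_age = stats::setNames(rep(0, length(bands)), bands),
    prs_referral_rate = 0, statin_prescription_rate = 0
  )
}

#' Apply one year of screening and statin initiation
#'
#' Eligible, still-untested persons in the primary-prevention pool attend
#' (per the HHC uptake for their age band, if the scenario requires a HHC),
#' are referred at the referral rate, and are tested: `tested_prs` grows by
#' the tested count (the test is one-off; the stock is absorbing). A
#' `top_fraction` of tests return high-PRS; of those, the prescription rate
#' start a statin and enter `on_statin`.
#'
#' @param state A `cad_population`.
#' @param scenario A `cad_scenario`.
#' @param risks Per-cell risk table from [cell_risks()] (uses `p5`).
#' @param top_fraction High-PRS fraction of tests (default 0.20).
#' @return List with `state` (updated), and per-cell vectors `prs_tests`,
#'   `statin_starts`, `hhc_visits`.
#' @export
apply_screening <- function(state, scenario, risks, top_fraction = 0.20) {
  validate_scenario(scenario)
  out <- tibble::as_tibble(state)
  lower <- band_lower_age(out$age_band)
  age_ok <- lower >= scenario$prs_age_min & lower <= scenario$prs_age_max
  frs_ok <- scenario$everyone_eligible |
    (risks$p5 <= scenario$frs_eligibility_max)
  uptake <- scenario$hhc_uptake_by_age[as.character(out$age_band)]
  if (anyNA(uptake)) stop("hhc_uptake_by_age missing an age band", call. = FALSE)

  untested <- pmax(out$primary_pool - out$tested_prs, 0)
  attenders <- untested * unname(uptake)
  hhc_visits <- ifelse(scenario$requires_hhc, 1, 0) * attenders
  tests <- attenders * age_ok * frs_ok * scenario$prs_referral_rate
  starts <- tests * top_fraction * scenario$statin_prescription_rate

  out$tested_prs <- out$tested_prs + tests
  out$on_statin <- out$on_statin + starts
  res <- new_population(out, calendar_year(state))
  list(state = res, prs_tests = tests, statin_starts = starts,
       hhc_visits = hhc_visits)
}

#' Apply one year of statin adherence and discontinuation
#'
#' Effective coverage this year is the treated stock times the age/sex
#' adherence fraction; the stock then shrinks by the annual
#' discontinuation probability. Scenarios with `full_adherence` bypass
#' both (coverage equals the stock, no discontinuation).
#'
#' @param on_statin Treated stock (vector, per cell).
#' @param sex,age_band Cell labels aligned with `on_statin`.
#' @param scenario A `cad_scenario`.
#' @return List with `covered` (effective person-years this year) and
#'   `stock_next` (stock after discontinuation).
#' @export
apply_adherence <- function(on_statin, sex, age_band, scenario) {
  if (scenario$full_adherence) {
    return(list(covered = on_statin, stock_next = on_statin))
  }
  key <- paste(as.character(sex), as.character(age_band))
  ad <- scenario$adherence_table
  adh <- ad$adherence[match(key, paste(ad$sex, ad$age_band))]
  dt <- scenario$discontinuation_table
  disc <- dt$discontinuation[match(key, paste(dt$sex, dt$age_band))]
  if (anyNA(adh) || anyNA(disc)) {
    bad <- unique(key[is.na(adh) | is.na(disc)])
    stop("adherence/discontinuation table missing stratum: ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  list(covered = on_statin * adh, stock_next = on_statin * (1 - disc))
}
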