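#' Expected incident acute coronary events in the primary-prevention pool
#'
#' Each cell's population is a mixture of a high-PRS stratum (fraction
#' `top_fraction`, probability `p_high`) and a low-PRS stratum
#' (`p_low`). Statin-covered person-years (all high-PRS by construction)
#' experience the treated probability instead of `p_high`. With zero
#' coverage the mixture recombines exactly to the undecomposed cell
#' probability.
#'
#' @param persons Primary-pool persons per cell (vector).
#' @param p_high,p_low,p_high_treated Per-cell probabilities from
#'   [cell_risks()].
#' @param top_fraction High-PRS population fraction.
#' @param covered Statin-covered person-years per cell; must not exceed
#'   `top_fraction * persons`.
#' @return Expected events per cell (vector).
#' @export
incident_aces <- function(persons, p_high, p_low, p_high_treated,
                          top_fraction, covered = 0) {
  covered <- rep_len(covered, length(persons))
  if (any(covered > top_fraction * persons + 1e-9)) {
    stop("covered person-years exceed the high-PRS stratum", call. = FALSE)
  }
  high <- top_fraction * persons
  covered * p_high_treated + (high - covered) * p_high +
    (1 - top_fraction) * persons * p_low
}

#' Split acute coronary events into OHCA and hospitalised pathways
#'
#' A fraction of events escalate to out-of-hospital cardiac arrest (OHCA)
#' with an initial survival probability; the remainder are hospitalised and
#' face a 30-day in-hospital mortality.
#'
#' @param aces Events (vector).
#' @param events_params Event parameter block ([default_event_params()]).
#' @return Tibble with columns `ohca_events`, `ohca_deaths`,
#'   `ohca_survivors`, `hospitalised`, `hospital_deaths`,
#'   `hospital_survivors`.
#' @export
split_ohca <- function(aces, events_params = default_event_params()) {
  stopifnot(all(aces >= 0))
  e <- events_params
  ohca <- aces * e$ohca_fraction
  ohca_deaths <- ohca * (1 - e$ohca_initial_survival)
  hosp <- aces - ohca
  hosp_deaths <- hosp * e$thirty_day_mortality
  tibble::tibble(
    ohca_events = ohca,
    ohca_deaths = ohca_deaths,
    ohca_survivors = ohca - ohca_deaths,
    hospitalised = hosp,
    hospital_deaths = hosp_deaths,
    hospital_survivors = hosp - hosp_deaths
  )
}

#' Deaths in the two-year post-event high-risk period
#'
#' Age-specific mortality is multiplied by 1.425 for men without OHCA,
#' 1.495 for women without OHCA, and 3.9 for either sex after an OHCA;
#' the product is clipped at 1.
#'
#' @param stock Persons in a post-event year-1/year-2 compartment (vector).
#' @param sex `"male"`/`"female"`, vectorised.
#' @param ohca Logical, did the index event involve an OHCA?
#' @param base_mortality Age-specific annual mortality (vector).
#' @param multipliers Named vector with `male_non_ohca`,
#'   `female_non_ohca`, `ohca_any_sex`.
#' @return Expected deaths (vector).
#' @export
high_risk_mortality <- function(stock, sex, ohca, base_mortality,
                                multipliers = default_event_params()$high_risk_multipliers) {
  n <- length(stock)
  sex <- rep_len(as.character(sex), n)
  ohca <- rep_len(ohca, n)
  if (!all(sex %in% c("male", "female"))) {
    stop("unknown sex level", call. = FALSE)
  }
  mult <- ifelse(ohca, multipliers[["ohca_any_sex"]],
                 ifelse(sex == "male", multipliers[["male_non_ohca"]],
                        multipliers[["female_non_ohca"]]))
  stock * pmin(1, mult * base_mortality)
}

#' Annual recurrence probability from a two-year probability
#'
#' Constant-hazard split of the two-year recurrence risk (25% within two
#' years of the index event): `1 - (1 - p2)^(1/2)`.
#'
#' @param two_year_prob Two-year probability in `[0, 1)`.
#' @return Annual probability.
#' @examples
#' annual_recurrence_prob(0.25) # 1 - sqrt(0.75)
#' @export
annual_recurrence_prob <- function(two_year_prob) {
  annualize(two_year_prob, 2)
}

#' Graduate survivors through the post-event high-risk compartments
#'
#' End-of-year bookkeeping: year-1 survivors move to year-2; year-2
#' survivors move to the prior-CHD pool. Persons are conserved.
#'
#' @param state A `cad_population`.
#' @return A `cad_population` with shifted high-risk stocks.
#' @export
graduate <- function(state) {
  out <- tibble::as_tibble(state)
  out$prior_chd <- out$prior_chd + out$post_ace_y2_ohca + out$post_ace_y2_nonohca
  out$post_ace_y2_ohca <- out$post_ace_y1_ohca
  out$post_ace_y2_nonohca <- out$post_ace_y1_nonohca
  out$post_ace_y1_ohca <- 0
  out$post_ace_y1_nonohca <- 0
  new_population(out, calendar_year(state))
}

# one annual cycle; returns list(state, flows-tibble for the year)
simulate_year <- function(state, scenario, params, risks, year) {
  e <- params$events
  f <- params$risk$prs_top_fraction

  # --- screening & statin initiation ---
  scr <- apply_screening(state, scenario, risks, f)
  st <- tibble::as_tibble(scr$state)

  # --- adherence: effective coverage this year, discontinuation at end ---
  adh <- apply_adherence(st$on_statin, st$sex, st$age_band, scenario)
  covered <- pmin(adh$covered, f * st$primary_pool)

  # --- incident events in the primary pool ---
  inc <- incident_aces(st$primary_pool, risks$p_high, risks$p_low,
                       risks$p_high_treated, f, covered)
  # statin stock's own events (adherent at treated risk, rest at p_high)
  stock_events <- covered * risks$p_high_treated +
    pmax(st$on_statin - covered, 0) * risks$p_high
  inc_rate <- ifelse(st$primary_pool > 0, inc / st$primary_pool, 0)

  # --- recurrent events: high-risk stocks and prior-CHD pool ---
  r_ann <- annual_recurrence_prob(e$two_year_recurrence)
  rec_y1o <- st$post_ace_y1_ohca * r_ann
  rec_y1n <- st$post_ace_y1_nonohca * r_ann
  rec_y2o <- st$post_ace_y2_ohca * r_ann
  rec_y2n <- st$post_ace_y2_nonohca * r_ann
  rec_chd <- st$prior_chd * risks$p_secondary
  recurrent <- rec_y1o + rec_y1n + rec_y2o + rec_y2n + rec_chd

  # --- acute outcomes ---
  sp_inc <- split_ohca(inc, e)
  if (e$recurrent_events_split_ohca) {
    sp_rec <- split_ohca(recurrent, e)
  } else {
    hosp_deaths <- recurrent * e$thirty_day_mortality
    sp_rec <- tibble::tibble(
      ohca_events = 0, ohca_deaths = 0, ohca_survivors = 0,
      hospitalised = recurrent, hospital_deaths = hosp_deaths,
      hospital_survivors = recurrent - hosp_deaths
    )
  }
  acute_deaths <- sp_inc$ohca_deaths + sp_inc$hospital_deaths +
    sp_rec$ohca_deaths + sp_rec$hospital_deaths

  # --- remove events from their source stocks ---
  prior_chd_py <- st$prior_chd           # person-years for chronic costs
  st$primary_pool <- st$primary_pool - inc
  st$on_statin <- pmax(st$on_statin - stock_events, 0)
  st$tested_prs <- pmax(st$tested_prs - st$tested_prs * inc_rate, 0)
  st$post_ace_y1_ohca <- st$post_ace_y1_ohca - rec_y1o
  st$post_ace_y1_nonohca <- st$post_ace_y1_nonohca - rec_y1n
  st$post_ace_y2_ohca <- st$post_ace_y2_ohca - rec_y2o
  st$post_ace_y2_nonohca <- st$post_ace_y2_nonohca - rec_y2n
  st$prior_chd <- st$prior_chd - rec_chd

  # --- excess high-risk mortality (base mortality is applied for every
  #     compartment in advance_demography; only the excess is an ACE death)
  q <- dplyr::left_join(
    dplyr::transmute(st, sex = as.character(.data$sex),
                     age_band = as.character(.data$age_band)),
    params$demography$non_ace_mortality, by = c("sex", "age_band")
  )$prob
  excess <- function(stock, ohca_flag) {
    total <- high_risk_mortality(stock, st$sex, ohca_flag, q,
                                 e$high_risk_multipliers)
    pmax(total - stock * q, 0)
  }
  ex_y1o <- excess(st$post_ace_y1_ohca, TRUE)
  ex_y1n <- excess(st$post_ace_y1_nonohca, FALSE)
  ex_y2o <- excess(st$post_ace_y2_ohca, TRUE)
  ex_y2n <- excess(st$post_ace_y2_nonohca, FALSE)
  st$post_ace_y1_ohca <- st$post_ace_y1_ohca - ex_y1o
  st$post_ace_y1_nonohca <- st$post_ace_y1_nonohca - ex_y1n
  st$post_ace_y2_ohca <- st$post_ace_y2_ohca - ex_y2o
  st$post_ace_y2_nonohca <- st$post_ace_y2_nonohca - ex_y2n
  excess_deaths <- ex_y1o + ex_y1n + ex_y2o + ex_y2n

  # --- graduation, then this year's survivors enter year 1 ---
  st <- tibble::as_tibble(graduate(new_population(st, calendar_year(state))))
  st$post_ace_y1_ohca <- st$post_ace_y1_ohca +
    sp_inc$ohca_survivors + sp_rec$ohca_survivors
  st$post_ace_y1_nonohca <- st$post_ace_y1_nonohca +
    sp_inc$hospital_survivors + sp_rec$hospital_survivors

  # --- demography: base mortality, ageing, inflow, migration ---
  nxt <- advance_demography(new_population(st, calendar_year(state)), params,
                            apply_mortality = TRUE)
  demo <- attr(nxt, "flows")

  flows <- tibble::tibble(
    year = year,
    cell_id = st$cell_id,
    sex = as.character(st$sex),
    age_band = as.character(st$age_band),
    ace_incident = inc,
    ace_recurrent = recurrent,
    ohca_events = sp_inc$ohca_events + sp_rec$ohca_events,
    ace_deaths = acute_deaths + excess_deaths,
    non_ace_deaths = demo$non_ace_deaths,
    prs_tests = scr$prs_tests,
    hhc_visits = scr$hhc_visits,
    statin_person_years = covered,
    prior_chd_person_years = prior_chd_py
  )

  # discontinuation takes effect for next year
  out <- tibble::as_tibble(nxt)
  if (!scenario$full_adherence) {
    disc <- apply_adherence(out$on_statin, out$sex, out$age_band, scenario)
    out$on_statin <- disc$stock_next
  }
  list(state = new_population(out, calendar_year(nxt)),
       flows = flows,
       inflow = demo$inflow, net_migration = demo$net_migration)
}

#' Simulate the population over a multi-year horizon
#'
#' Runs the annual cycle (screening, adherence, incident and recurrent
#' events, acute mortality, excess high-risk mortality, graduation,
#' demography) for `years` years. The model is deterministic given its
#' inputs: identical arguments give bit-identical trajectories.
#'
#' @param state0 Initial `cad_population` (see [synthesize_population()]).
#' @param scenario A `cad_scenario`; use [baseline_scenario()] for the
#'   no-intervention baseline.
#' @param params A `cad_params` object.
#' @param years Horizon length (default 10).
#' @param odds_ratio PRS odds ratio used for the risk decomposition
#'   (default from `params`).
#' @return A list of class `cad_trajectory`: `flows` (tidy per-cell,
#'   per-year tibble), `final_state`, `yearly` (per-year totals incl.
#'   inflow/migration for conservation checks), `scenario`, `odds_ratio`.
#' @export
simulate_horizon <- function(state0, scenario, params = default_parameters(),
                             years = 10,
                             odds_ratio = params$risk$prs_odds_ratio) {
  validate_parameters(params)
  validate_scenario(scenario)
  risks <- cell_risks(dplyr::select(tibble::as_tibble(state0),
                                    "cell_id", dplyr::all_of(cell_key_cols())),
                      params, odds_ratio = odds_ratio)
  state <- state0
  flows <- vector("list", years)
  yearly <- vector("list", years)
  for (y in seq_len(years)) {
    step <- simulate_year(state, scenario, params, risks, y)
    flows[[y]] <- step$flows
    yearly[[y]] <- tibble::tibble(
      year = y,
      persons_start = total_persons(state),
      persons_end = total_persons(step$state),
      inflow = step$inflow,
      net_migration = step$net_migration,
      ace_cases = sum(step$flows$ace_incident + step$flows$ace_recurrent),
      ace_deaths = sum(step$flows$ace_deaths),
      non_ace_deaths = sum(step$flows$non_ace_deaths),
      prs_tests = sum(step$flows$prs_tests)
    )
    state <- step$state
  }
  structure(list(
    flows = dplyr::bind_rows(flows),
    yearly = dplyr::bind_rows(yearly),
    final_state = state,
    scenario = scenario$name,
    odds_ratio = odds_ratio,
    years = years
  ), class = "cad_trajectory")
}

#' @export
print.cad_trajectory <- function(x, ...) {
  cat("<cad_trajectory> scenario:", x$scenario,
      " years:", x$years, " OR:", x$odds_ratio, "\n")
  cat(sprintf("  cumulative ACE cases: %.0f  ACE deaths: %.0f  PRS tests: %.0f\n",
              sum(x$yearly$ace_cases), sum(x$yearly$ace_deaths),
              sum(x$yearly$prs_tests)))
  invisible(x)
}

#' Write a trajectory's flows as tidy CSV
#' @param trajectory A `cad_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  long <- tidyr::pivot_longer(
    trajectory$flows,
    cols = -c("year", "cell_id", "sex", "age_band"),
    names_to = "flow", values_to = "value"
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
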