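#' Default run configuration
#'
#' A run configuration drives the whole pipeline reproducibly: RNG seed,
#' horizon, scenario selection, population size and method, odds-ratio
#' bracket, output directory, and optional overrides of any parameter
#' block. Serializable to YAML.
#'
#' @param ... Fields overriding the defaults.
#' @return A named list of class `cad_run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- structure(list(
    seed = 1L,
    years = 10L,
    scenario = "all",                 # maximal | intermediate | targeted | all
    population_size = 20.6e6,
    population_method = "expected",   # or "multinomial"
    odds_ratio = 1.9,
    or_ci = c(1.8, 2.0),
    output_dir = "cadprs_run",
    parameters = list()               # nested overrides of default_parameters()
  ), class = "cad_run_config")
  utils::modifyList(cfg, list(...))
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @return A validated `cad_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_run_config(), raw)
  # YAML readers return plain-style scientific notation ("2.0e6") as text
  for (f in c("population_size", "odds_ratio", "or_ci")) {
    cfg[[f]] <- as.numeric(cfg[[f]])
  }
  for (f in c("seed", "years")) cfg[[f]] <- as.integer(cfg[[f]])
  validate_run_config(cfg)
  cfg
}

#' Write a run configuration to YAML
#' @param config A `cad_run_config`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate a run configuration
#'
#' Checks field presence, types and ranges; errors name the first failing
#' field.
#'
#' @param config A `cad_run_config`.
#' @return `config`, invisibly.
#' @export
validate_run_config <- function(config) {
  fail <- function(field, why) {
    stop("invalid run config: field '", field, "' ", why, call. = FALSE)
  }
  req <- c("seed", "years", "scenario", "population_size",
           "population_method", "odds_ratio", "or_ci", "output_dir")
  for (f in req) if (is.null(config[[f]])) fail(f, "is missing")
  if (config$years < 1) fail("years", "must be >= 1")
  if (config$population_size <= 0) fail("population_size", "must be > 0")
  if (!config$population_method %in% c("expected", "multinomial")) {
    fail("population_method", "must be 'expected' or 'multinomial'")
  }
  if (config$odds_ratio <= 0) fail("odds_ratio", "must be > 0")
  if (length(config$or_ci) != 2 || any(config$or_ci <= 0)) {
    fail("or_ci", "must be two positive odds ratios")
  }
  known <- c("maximal", "intermediate", "targeted", "all")
  if (!(config$scenario %in% known || file.exists(config$scenario))) {
    fail("scenario", "must be one of maximal/intermediate/targeted/all or a YAML file")
  }
  invisible(config)
}

resolve_run_parameters <- function(config) {
  params <- default_parameters()
  ov <- config$parameters
  for (nm in names(ov)) {
    if (is.list(params[[nm]]) && is.list(ov[[nm]])) {
      params[[nm]] <- utils::modifyList(params[[nm]], ov[[nm]])
    } else {
      params[[nm]] <- ov[[nm]]
    }
  }
  params$risk$prs_odds_ratio <- config$odds_ratio
  params$risk$prs_or_ci <- config$or_ci
  validate_parameters(params)
  params
}

resolve_scenarios <- function(config) {
  sc <- builtin_scenarios()
  if (identical(config$scenario, "all")) return(sc)
  if (config$scenario %in% names(sc)) return(sc[config$scenario])
  spec <- yaml::read_yaml(config$scenario)
  spec$adherence_table <- if (is.null(spec$adherence_table)) {
    default_adherence_table()
  } else tibble::as_tibble(spec$adherence_table)
  spec$discontinuation_table <- if (is.null(spec$discontinuation_table)) {
    default_discontinuation_table()
  } else tibble::as_tibble(spec$discontinuation_table)
  out <- list(do.call(scenario_config, spec))
  stats::setNames(out, out[[1]]$name)
}

#' Run the full pipeline from a configuration and write artifacts
#'
#' Synthesizes the population, simulates the baseline and the configured
#' scenario(s) over the horizon with the odds-ratio bracket, and writes to
#' `output_dir`: per-scenario trajectory CSVs, a Table-1-style overall
#' measures CSV, a Table-2-style by-sex CSV, a JSON summary with
#' provenance, and the fully resolved configuration YAML. Identical
#' configurations produce byte-identical CSV artifacts.
#'
#' @param config A `cad_run_config`, or path to a YAML file.
#' @return Invisibly, a list with the `cad_econ` results and artifact
#'   paths.
#' @export
run_model <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  params <- resolve_run_parameters(config)
  scenarios <- resolve_scenarios(config)

  message("cadprs run: seed=", config$seed, " years=", config$years,
          " population=", format(config$population_size, big.mark = ","),
          " OR=", config$odds_ratio,
          " [", config$or_ci[1], "-", config$or_ci[2], "]",
          " scenarios=", paste(names(scenarios), collapse = ","))

  state0 <- synthesize_population(params, config$population_size,
                                  seed = config$seed,
                                  method = config$population_method)
  baseline_traj <- simulate_horizon(state0, baseline_scenario(), params,
                                    config$years)
  results <- lapply(scenarios, function(sc) {
    evaluate_scenario(state0, sc, params, years = config$years,
                      odds_ratio = config$odds_ratio, or_ci = config$or_ci,
                      baseline_traj = baseline_traj)
  })

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(results)) {
    traj <- simulate_horizon(state0, scenarios[[nm]], params, config$years,
                             odds_ratio = config$odds_ratio)
    p <- file.path(config$output_dir, paste0("trajectory_", nm, ".csv"))
    write_trajectory_csv(traj, p)
    paths <- c(paths, p)
  }
  t1 <- report_table1(results)
  p1 <- file.path(config$output_dir, "table1.csv")
  utils::write.csv(t1, p1, row.names = FALSE)
  t2 <- report_table2(results)
  p2 <- file.path(config$output_dir, "table2.csv")
  utils::write.csv(t2, p2, row.names = FALSE)

  summary <- list(
    provenance = list(
      seed = config$seed, years = config$years,
      population_size = config$population_size,
      population_method = config$population_method,
      odds_ratio = config$odds_ratio, or_ci = config$or_ci,
      package_version = as.character(utils::packageVersion("cadprs"))
    ),
    baseline = results[[1]]$baseline,
    measures = dplyr::bind_rows(lapply(results, tidy))
  )
  pj <- file.path(config$output_dir, "summary.json")
  jsonlite::write_json(summary, pj, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  pc <- file.path(config$output_dir, "resolved_config.yaml")
  write_run_config(config, pc)

  for (r in results) {
    g <- glance(r)
    message(sprintf(
      "  %s: QALYs %.0f, net cost $%.0fm, $%.0f/QALY, net benefit $%.0fm",
      g$scenario, g$qalys_gained, g$net_cost, g$cost_per_qaly, g$net_benefit))
  }
  invisible(list(results = results,
                 artifacts = c(paths, p1, p2, pj, pc),
                 baseline_traj = baseline_traj))
}

#' Table-1-style report: overall measures, baseline plus scenarios
#'
#' @param results List of `cad_econ` objects (as from [run_model()]).
#' @return Tibble with one row per measure: baseline value (where defined)
#'   and, per scenario, the point estimate with `[low, high]` odds-ratio
#'   bounds.
#' @export
report_table1 <- function(results) {
  base <- results[[1]]$baseline
  rows <- dplyr::bind_rows(lapply(results, function(x) {
    dplyr::mutate(x$measures[x$measures$sex == "overall", ],
                  scenario = x$scenario)
  }))
  wide <- tidyr::pivot_wider(
    dplyr::select(rows, "measure", "scenario", "estimate", "low", "high"),
    names_from = "scenario",
    values_from = c("estimate", "low", "high"),
    names_glue = "{scenario}_{.value}"
  )
  wide$baseline <- base$value[match(wide$measure, base$measure)]
  dplyr::relocate(wide[match(ECON_MEASURES, wide$measure), ],
                  "measure", "baseline")
}

#' Table-2-style report: measures by sex
#'
#' @param results List of `cad_econ` objects.
#' @return Tidy tibble: scenario, measure, sex, estimate, low, high.
#' @export
report_table2 <- function(results) {
  dplyr::bind_rows(lapply(results, function(x) {
    dplyr::mutate(
      dplyr::select(
        dplyr::filter(x$measures, .data$sex != "overall"),
        "measure", "sex", "estimate", "low", "high"
      ),
      scenario = x$scenario, .before = 1
    )
  }))
}

#' Compare two completed runs written by [run_model()]
#'
#' Reads both runs' JSON summaries, refuses to compare runs with different
#' provenance (seed, population, horizon), and returns the per-measure
#' deltas (scenario minus baseline-relative measures of run B minus run A).
#'
#' @param dir_a,dir_b Output directories of two runs.
#' @return Tibble of measure deltas by scenario and sex.
#' @export
compare_runs <- function(dir_a, dir_b) {
  read_sum <- function(d) jsonlite::read_json(file.path(d, "summary.json"),
                                              simplifyVector = TRUE)
  a <- read_sum(dir_a)
  b <- read_sum(dir_b)
  keys <- c("seed", "years", "population_size", "population_method")
  mismatch <- keys[!vapply(keys, function(k) {
    identical(a$provenance[[k]], b$provenance[[k]])
  }, logical(1))]
  if (length(mismatch) > 0) {
    stop("runs are not comparable; provenance differs in: ",
         paste(mismatch, collapse = ", "), "\n  A: ",
         paste(unlist(a$provenance[mismatch]), collapse = ", "), "\n  B: ",
         paste(unlist(b$provenance[mismatch]), collapse = ", "),
         call. = FALSE)
  }
  ma <- tibble::as_tibble(a$measures)
  mb <- tibble::as_tibble(b$measures)
  dplyr::mutate(
    dplyr::inner_join(ma, mb, by = c("scenario", "measure", "sex"),
                      suffix = c("_a", "_b")),
    delta = .data$estimate_b - .data$estimate_a
  )
}
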