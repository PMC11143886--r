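# Shared fixtures, built in code and memoised so expensive objects are
# computed once per test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

default_params_fixture <- function() memo("params", default_parameters())

# Default-size synthetic population (deterministic expected counts).
default_pop_fixture <- function() {
  memo("pop", synthesize_population(default_params_fixture(), seed = 1))
}

baseline_traj_fixture <- function(years = 10) {
  memo(paste0("base", years),
       simulate_horizon(default_pop_fixture(), baseline_scenario(),
                        default_params_fixture(), years))
}

scenario_econ_fixture <- function(name, years = 10) {
  memo(paste0("econ_", name, "_", years), {
    evaluate_scenario(default_pop_fixture(), builtin_scenarios()[[name]],
                      default_params_fixture(), years = years,
                      baseline_traj = baseline_traj_fixture(years))
  })
}

# Demography with no inflow, no migration, optional mortality override:
# isolates event/ageing dynamics.
closed_demography <- function(params, mortality = 0) {
  d <- params$demography
  d$inflow_by_sex <- c(male = 0, female = 0)
  d$net_migration$persons <- 0
  d$non_ace_mortality$prob <- mortality
  params$demography <- d
  params
}

# A population that is empty except for chosen cells.
toy_state <- function(cell_ids, primary = 0, prior_chd = 0,
                      y1_ohca = 0, y1_non = 0, y2_ohca = 0, y2_non = 0,
                      on_statin = 0, tested = 0) {
  cells <- cad_cells()
  tbl <- dplyr::mutate(
    cells,
    primary_pool = 0, post_ace_y1_ohca = 0, post_ace_y1_nonohca = 0,
    post_ace_y2_ohca = 0, post_ace_y2_nonohca = 0, prior_chd = 0,
    tested_prs = 0, on_statin = 0
  )
  put <- function(col, v) {
    v <- rep_len(v, length(cell_ids))
    tbl[[col]][cell_ids] <<- v
    invisible(NULL)
  }
  put("primary_pool", primary); put("prior_chd", prior_chd)
  put("post_ace_y1_ohca", y1_ohca); put("post_ace_y1_nonohca", y1_non)
  put("post_ace_y2_ohca", y2_ohca); put("post_ace_y2_nonohca", y2_non)
  put("on_statin", on_statin); put("tested_prs", tested)
  cadprs:::new_population(tbl, 0L)
}

# Independent scalar oracle for the PRS decomposition (uniroot, not the
# package's vectorised bisection).
decompose_oracle <- function(p, or, f) {
  if (p == 0) return(c(p_high = 0, p_low = 0))
  ph_of <- function(pl) {
    o <- or * pl / (1 - pl)
    o / (1 + o)
  }
  ub <- if (or >= 1) p else (p + 1) / 2
  pl <- stats::uniroot(function(pl) f * ph_of(pl) + (1 - f) * pl - p,
                       c(0, ub), tol = 1e-15)$root
  c(p_high = ph_of(pl), p_low = pl)
}

# cell_id of the first cell matching the given key values
find_cell <- function(...) {
  keys <- list(...)
  cells <- cad_cells()
  sel <- rep(TRUE, nrow(cells))
  for (nm in names(keys)) sel <- sel & cells[[nm]] == keys[[nm]]
  cells$cell_id[which(sel)[1]]
}
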