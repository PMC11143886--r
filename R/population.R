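COMPARTMENTS <- c("primary_pool", "post_ace_y1_ohca", "post_ace_y1_nonohca",
                  "post_ace_y2_ohca", "post_ace_y2_nonohca", "prior_chd")
SUBSTOCKS <- c("tested_prs", "on_statin")

compartment_cols <- function() COMPARTMENTS

new_population <- function(tbl, calendar_year = 0L) {
  stopifnot(all(c("cell_id", cell_key_cols(), COMPARTMENTS, SUBSTOCKS)
                %in% names(tbl)))
  structure(tbl, calendar_year = as.integer(calendar_year),
            class = c("cad_population", class(tibble::tibble())))
}

#' Total persons in a population state
#'
#' Sums the six person compartments (the `tested_prs` / `on_statin`
#' sub-stocks are markers within `primary_pool`, not extra persons).
#'
#' @param state A `cad_population`.
#' @return Total person count (scalar).
#' @export
total_persons <- function(state) {
  sum(vapply(COMPARTMENTS, function(cc) sum(state[[cc]]), numeric(1)))
}

#' Calendar year of a population state
#' @param state A `cad_population`.
#' @return Integer year index (0 at synthesis).
#' @export
calendar_year <- function(state) attr(state, "calendar_year")

# P(cell | sex, age_band) from the independent per-factor margins.
conditional_cell_probs <- function(cells, demography) {
  fm <- demography$factor_margins
  probs <- rep(1, nrow(cells))
  key <- paste(as.character(cells$sex), as.character(cells$age_band))
  for (fac in unique(fm$factor)) {
    sub <- fm[fm$factor == fac, ]
    lv <- as.character(cells[[fac]])
    idx <- match(paste(fac, key, lv),
                 paste(sub$factor, sub$sex, sub$age_band, sub$level))
    if (anyNA(idx)) {
      stop("prevalence margins missing levels for factor: ", fac,
           call. = FALSE)
    }
    p <- sub$prob[idx]
    if (any(p < 0)) {
      stop("negative prevalence margin for factor: ", fac, call. = FALSE)
    }
    probs <- probs * p
  }
  probs
}

#' Generate a synthetic population state
#'
#' Allocates `total_persons` across the 10,368 risk cells by combining the
#' age-by-sex margins with independent sampling of each risk factor from
#' its prevalence margins within the age-by-sex stratum (the independence
#' assumption is a documented simplification). A configurable fraction per
#' age band is seeded into the prior-CHD compartment; everyone else starts
#' in the primary-prevention pool, untested.
#'
#' @param params A `cad_params` object (its `demography` block is used).
#' @param total_persons Total adult population (default from the
#'   demography block).
#' @param seed Integer RNG seed; identical seeds give identical states.
#' @param method `"expected"` (real-valued expected counts, the
#'   deterministic stock-and-flow default) or `"multinomial"` (integer
#'   counts drawn from one multinomial).
#' @return A `cad_population` tibble (cells x compartments) at calendar
#'   year 0.
#' @export
synthesize_population <- function(params = default_parameters(),
                                  total_persons = params$demography$total_persons,
                                  seed = 1L,
                                  method = c("expected", "multinomial")) {
  method <- match.arg(method)
  stopifnot(total_persons > 0)
  validate_parameters(params)
  d <- params$demography
  cells <- cad_cells()

  asm <- d$age_sex_margins
  as_idx <- match(paste(as.character(cells$sex), as.character(cells$age_band)),
                  paste(asm$sex, asm$age_band))
  prob <- asm$prob[as_idx] * conditional_cell_probs(cells, d)
  prob <- prob / sum(prob)

  counts <- if (method == "expected") {
    total_persons * prob
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    as.numeric(stats::rmultinom(1, size = round(total_persons), prob = prob))
  }

  seed_frac <- d$prior_chd_seed[as.character(cells$age_band)]
  tbl <- dplyr::mutate(
    cells,
    primary_pool = counts * (1 - unname(seed_frac)),
    post_ace_y1_ohca = 0, post_ace_y1_nonohca = 0,
    post_ace_y2_ohca = 0, post_ace_y2_nonohca = 0,
    prior_chd = counts * unname(seed_frac),
    tested_prs = 0, on_statin = 0
  )
  new_population(tbl, 0L)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# cell_id of the cell with the same keys but the next-older age band
# (NA for 75+). The grid layout is fixed, so compute once per session.
next_band_index <- local({
  cache <- NULL
  function(cells) {
    if (!is.null(cache)) return(cache)
    bands <- cell_levels()$age_band
    key_now <- do.call(paste, c(cells[setdiff(cell_key_cols(), "age_band")],
                                list(as.character(cells$age_band))))
    nxt <- bands[pmin(match(as.character(cells$age_band), bands) + 1,
                      length(bands))]
    key_next <- do.call(paste, c(cells[setdiff(cell_key_cols(), "age_band")],
                                 list(nxt)))
    idx <- match(key_next, key_now)
    idx[as.character(cells$age_band) == "75+"] <- NA_integer_
    cache <<- idx
    idx
  }
})

# Yearly graduation fraction out of each age band (1/band width in years).
ageing_fraction <- function(age_band) {
  unname(c("20-34" = 1 / 15, "35-44" = 1 / 10, "45-54" = 1 / 10,
           "55-64" = 1 / 10, "65-74" = 1 / 10,
           "75+" = 0)[as.character(age_band)])
}

#' Advance the demography of a population state by one year
#'
#' Applies, in order: non-ACE mortality to every compartment (including
#' prior-CHD and the tested/treated sub-stocks), ageing (a fraction
#' 1/band-width of every stock graduates to the next age band, carrying
#' tested/treated status proportionally), inflow of 20-34-year-olds into
#' the primary pool, and net migration scaled across each age-by-sex
#' stratum's current composition. Returns a new state; the input is not
#' modified.
#'
#' @param state A `cad_population`.
#' @param params A `cad_params` object.
#' @param apply_mortality If `FALSE`, skip the mortality step (used by
#'   [simulate_horizon()], which accounts for deaths in its event stage).
#' @return A `cad_population` one calendar year later, with attribute
#'   `flows` (a list with `non_ace_deaths` per cell, `inflow`,
#'   `net_migration`).
#' @export
advance_demography <- function(state, params, apply_mortality = TRUE) {
  d <- params$demography
  cols <- c(COMPARTMENTS, SUBSTOCKS)
  out <- tibble::as_tibble(state)

  q <- dplyr::left_join(
    dplyr::transmute(out, sex = as.character(.data$sex),
                     age_band = as.character(.data$age_band)),
    d$non_ace_mortality, by = c("sex", "age_band")
  )$prob
  if (any(q < 0 | q > 1)) {
    stop("non-ACE mortality probabilities must be in [0, 1]", call. = FALSE)
  }
  non_ace_deaths <- rep(0, nrow(out))
  if (apply_mortality) {
    for (cc in COMPARTMENTS) non_ace_deaths <- non_ace_deaths + out[[cc]] * q
    for (cc in cols) out[[cc]] <- out[[cc]] * (1 - q)
  }

  g <- ageing_fraction(out$age_band)
  idx <- next_band_index(out)
  from <- which(!is.na(idx))
  for (cc in cols) {
    moved <- out[[cc]] * g
    new <- out[[cc]] - moved
    new[idx[from]] <- new[idx[from]] + moved[from]
    out[[cc]] <- new
  }

  inflow_total <- 0
  cond <- conditional_cell_probs(out, d)
  for (s in names(d$inflow_by_sex)) {
    sel <- as.character(out$sex) == s & as.character(out$age_band) == "20-34"
    w <- cond[sel] / sum(cond[sel])
    out$primary_pool[sel] <- out$primary_pool[sel] + d$inflow_by_sex[[s]] * w
    inflow_total <- inflow_total + d$inflow_by_sex[[s]]
  }

  mig <- d$net_migration
  mig_total <- 0
  strat <- paste(as.character(out$sex), as.character(out$age_band))
  persons_strat <- tapply(rowSums(out[COMPARTMENTS]), strat, sum)
  for (i in seq_len(nrow(mig))) {
    key <- paste(mig$sex[i], mig$age_band[i])
    tot <- persons_strat[[key]]
    if (mig$persons[i] == 0) next
    if (is.na(tot) || tot <= 0) next
    fac <- 1 + mig$persons[i] / tot
    if (fac < 0) fac <- 0
    sel <- strat == key
    for (cc in cols) out[[cc]][sel] <- out[[cc]][sel] * fac
    mig_total <- mig_total + mig$persons[i]
  }

  res <- new_population(out, calendar_year(state) + 1L)
  attr(res, "flows") <- list(non_ace_deaths = non_ace_deaths,
                             inflow = inflow_total,
                             net_migration = mig_total)
  res
}

#' Serialize a population state to tidy CSV
#'
#' One row per cell-by-stock combination: all nine key fields, the stock
#' name (six person compartments plus the `tested_prs` / `on_statin`
#' sub-stocks), the count, and the calendar year. Round-trips losslessly
#' through [read_population_csv()].
#'
#' @param state A `cad_population`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(state, path) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(state),
    cols = dplyr::all_of(c(COMPARTMENTS, SUBSTOCKS)),
    names_to = "compartment", values_to = "count"
  )
  long$calendar_year <- calendar_year(state)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a population state written by [write_population_csv()]
#' @param path CSV file.
#' @return A `cad_population`.
#' @export
read_population_csv <- function(path) {
  long <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  year <- unique(long$calendar_year)
  stopifnot(length(year) == 1)
  wide <- tidyr::pivot_wider(
    dplyr::select(long, -"calendar_year"),
    names_from = "compartment", values_from = "count"
  )
  lv <- cell_levels()
  wide <- dplyr::mutate(
    wide,
    sex = factor(.data$sex, levels = lv$sex),
    age_band = factor(.data$age_band, levels = lv$age_band, ordered = TRUE),
    tc_level = factor(.data$tc_level, levels = lv$tc_level, ordered = TRUE),
    hdl_level = factor(.data$hdl_level, levels = lv$hdl_level, ordered = TRUE),
    sbp_level = factor(.data$sbp_level, levels = lv$sbp_level, ordered = TRUE),
    diabetes = factor(.data$diabetes, levels = lv$diabetes),
    smoking = factor(.data$smoking, levels = lv$smoking)
  )
  wide <- dplyr::arrange(wide, .data$cell_id)
  new_population(wide, year)
}

#' Serialize a population state to a JSON snapshot
#'
#' @param state A `cad_population`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_population_json <- function(state, path) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(state),
    cols = dplyr::all_of(c(COMPARTMENTS, SUBSTOCKS)),
    names_to = "compartment", values_to = "count"
  )
  long <- dplyr::mutate(long, dplyr::across(dplyr::where(is.factor),
                                            as.character))
  jsonlite::write_json(
    list(calendar_year = calendar_year(state), counts = long),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a population snapshot written by [write_population_json()]
#' @param path JSON file.
#' @return A `cad_population`.
#' @export
read_population_json <- function(path) {
  snap <- jsonlite::read_json(path, simplifyVector = TRUE)
  long <- tibble::as_tibble(snap$counts)
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  long$calendar_year <- snap$calendar_year
  utils::write.csv(long, tmp, row.names = FALSE)
  read_population_csv(tmp)
}
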