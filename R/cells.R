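#' Risk-cell stratification of the adult population
#'
#' The simulated population (ages 20+) is partitioned into homogeneous risk
#' cells by sex, age band, total cholesterol (3 levels, treated or not), HDL
#' cholesterol (2 levels), systolic blood pressure (4 levels, treated or
#' not), diabetes status (normal glucose regulation, impaired glucose
#' tolerance, type 2 diabetes) and smoking status (never, ex, current).
#' The full cross-product yields 2 x 6 x (3 x 2) x 2 x (4 x 2) x 3 x 3 =
#' 10,368 cells.
#'
#' @return A tibble with one row per risk cell in a fixed deterministic
#'   order (later columns vary fastest), with an integer `cell_id` and the
#'   nine key columns as factors/logicals.
#' @examples
#' cells <- cad_cells()
#' nrow(cells) # 10368
#' @export
cad_cells <- function() {
  lv <- cell_levels()
  cells <- tidyr::expand_grid(
    sex = factor(lv$sex, levels = lv$sex),
    age_band = factor(lv$age_band, levels = lv$age_band, ordered = TRUE),
    tc_level = factor(lv$tc_level, levels = lv$tc_level, ordered = TRUE),
    tc_treated = c(FALSE, TRUE),
    hdl_level = factor(lv$hdl_level, levels = lv$hdl_level, ordered = TRUE),
    sbp_level = factor(lv$sbp_level, levels = lv$sbp_level, ordered = TRUE),
    sbp_treated = c(FALSE, TRUE),
    diabetes = factor(lv$diabetes, levels = lv$diabetes),
    smoking = factor(lv$smoking, levels = lv$smoking)
  )
  dplyr::mutate(cells, cell_id = dplyr::row_number(), .before = 1)
}

#' Factor levels of the risk-cell stratification
#'
#' @return Named list of the level labels of each stratification variable.
#' @export
cell_levels <- function() {
  list(
    sex = c("male", "female"),
    age_band = c("20-34", "35-44", "45-54", "55-64", "65-74", "75+"),
    tc_level = c("tc_low", "tc_mid", "tc_high"),
    hdl_level = c("hdl_low", "hdl_high"),
    sbp_level = c("sbp_1", "sbp_2", "sbp_3", "sbp_4"),
    diabetes = c("ngr", "igt", "t2dm"),
    smoking = c("never", "ex", "current")
  )
}

# Key columns identifying a cell, in canonical order.
cell_key_cols <- function() {
  c("sex", "age_band", "tc_level", "tc_treated", "hdl_level",
    "sbp_level", "sbp_treated", "diabetes", "smoking")
}

#' Representative continuous values for each categorical risk-factor level
#'
#' The risk engine needs continuous covariates (age in years, lipids in
#' mg/dL, SBP in mmHg). Each categorical level maps to a configurable
#' representative value; these defaults are synthetic choices documented in
#' the methods vignette (the level cut-points of the original survey data
#' are not published).
#'
#' @return Named list of named numeric vectors, plus mapping flags for
#'   diabetes (`igt_is_diabetic`) and smoking (`ex_is_smoker`).
#' @export
default_representative_values <- function() {
  list(
    age_years = c("20-34" = 27, "35-44" = 40, "45-54" = 50,
                  "55-64" = 60, "65-74" = 70, "75+" = 80),
    tc = c(tc_low = 180, tc_mid = 220, tc_high = 260),     # mg/dL
    hdl = c(hdl_low = 40, hdl_high = 60),                   # mg/dL
    sbp = c(sbp_1 = 115, sbp_2 = 130, sbp_3 = 145, sbp_4 = 165), # mmHg
    igt_is_diabetic = FALSE,
    ex_is_smoker = FALSE
  )
}

#' Derive continuous risk-factor profiles from risk-cell keys
#'
#' Deterministically expands the categorical cell keys into the continuous
#' covariates consumed by [framingham_risk()].
#'
#' @param cells A tibble containing the cell key columns (e.g. from
#'   [cad_cells()]).
#' @param rep_values Representative-value map, see
#'   [default_representative_values()].
#' @return `cells` with columns `age_years`, `tc`, `hdl`, `sbp`,
#'   `sbp_rx` (on antihypertensive treatment), `diabetic`, `smoker` added.
#' @export
cell_profiles <- function(cells, rep_values = default_representative_values()) {
  stopifnot(all(cell_key_cols() %in% names(cells)))
  dplyr::mutate(
    cells,
    age_years = unname(rep_values$age_years[as.character(.data$age_band)]),
    tc = unname(rep_values$tc[as.character(.data$tc_level)]),
    hdl = unname(rep_values$hdl[as.character(.data$hdl_level)]),
    sbp = unname(rep_values$sbp[as.character(.data$sbp_level)]),
    sbp_rx = .data$sbp_treated,
    diabetic = .data$diabetes == "t2dm" |
      (rep_values$igt_is_diabetic & .data$diabetes == "igt"),
    smoker = .data$smoking == "current" |
      (rep_values$ex_is_smoker & .data$smoking == "ex")
  )
}
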