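# Baseline mortality and disease-specific relative-risk adjustment.

#' Gompertz baseline life table
#'
#' Builds an age-indexed table of annual death probabilities for the general
#' population from a Gompertz hazard, `q(x) = 1 - exp(-a * exp(b * x))`.
#' The defaults (`a = 2.8e-5`, `b = 0.09`) are calibrated to plausible
#' East-Asian adult mortality and stand in for a national period life
#' table; supply one through [read_life_table()] for a reproduction
#' against published mortality.
#'
#' @param a Baseline hazard at age 0 (must be positive).
#' @param b Log-hazard slope per year of age (must be positive).
#' @param max_age Last age in the table.
#' @return A tibble of class `pdr_life_table` with columns `age` and `q`
#'   (annual probability of death).
#' @examples
#' lt <- gompertz_life_table()
#' lt$q[lt$age == 50]  # ~0.00252
#' @export
gompertz_life_table <- function(a = 2.8e-5, b = 0.09, max_age = 100) {
  if (a < 0) stop("baseline hazard `a` must be non-negative", call. = FALSE)
  if (b <= 0) stop("slope `b` must be positive", call. = FALSE)
  age <- 0:max_age
  q <- 1 - exp(-a * exp(b * age))
  new_life_table(tibble::tibble(age = age, q = q))
}

new_life_table <- function(tbl) {
  structure(tbl, class = c("pdr_life_table", "tbl_df", "tbl", "data.frame"))
}

#' Read a life table from a two-column file
#'
#' Expects headered tabular text with columns `age` (integer years) and `q`
#' (annual death probability). The table must cover the simulation horizon.
#'
#' @param path Path to a CSV/TSV file.
#' @return A `pdr_life_table` tibble.
#' @export
read_life_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("age", "q") %in% names(tbl)))
    stop("life table must have columns `age` and `q`", call. = FALSE)
  tbl <- dplyr::arrange(tbl[, c("age", "q")], .data$age)
  if (any(tbl$q < 0 | tbl$q > 1))
    stop("life-table death probabilities must lie in [0, 1]", call. = FALSE)
  if (any(duplicated(tbl$age)))
    stop("life table has duplicated ages", call. = FALSE)
  new_life_table(tbl)
}

#' Write a life table to CSV
#'
#' @param lt A `pdr_life_table` tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_life_table <- function(lt, path) {
  readr::write_csv(tibble::as_tibble(lt), path)
  invisible(path)
}

# Baseline q at the requested ages, with a range check.
baseline_q <- function(lt, ages) {
  idx <- match(ages, lt$age)
  if (anyNA(idx))
    stop("life table does not cover age(s) ",
         paste(ages[is.na(idx)], collapse = ", "), call. = FALSE)
  lt$q[idx]
}

#' Annual death probability in a model state
#'
#' Applies the diabetes mortality relative risk to the general-population
#' annual death probability, and additionally the severe-visual-loss (SVL)
#' relative risk for SVL occupants; the product is capped at 1. The SVL RR
#' multiplies the already diabetes-adjusted probability (the published
#' contrast is SVL vs non-SVL within the diabetic cohort).
#'
#' @param q_gen General-population annual death probability in \[0, 1\]
#'   (vectorised).
#' @param params A `pdr_params` tibble or named value list.
#' @param is_svl Is the occupant in the SVL state? (vectorised)
#' @return Adjusted annual death probability in \[0, 1\].
#' @examples
#' state_death_prob(0.01, default_parameters(), is_svl = FALSE)  # 0.0149
#' @export
state_death_prob <- function(q_gen, params, is_svl = FALSE) {
  if (any(q_gen < 0 | q_gen > 1))
    stop("q_gen must lie in [0, 1]", call. = FALSE)
  plist <- if (inherits(params, "pdr_params")) param_values(params) else params
  rr <- pv(plist, "rr_death_diabetes") *
    ifelse(is_svl, pv(plist, "rr_death_SVL"), 1)
  pmin(1, q_gen * rr)
}
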