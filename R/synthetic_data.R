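# Synthetic stand-ins for the model's non-public inputs: claims-like cost
# episodes for macro-costing, EQ-5D-like utility survey responses, and the
# Gompertz life-table fixture (see gompertz_life_table()). All generators
# are deterministic under a seed and emulate structure only — per-record
# dispersion choices are configuration, not estimates from the real data.

#' Generate claims-like annual cost episode records
#'
#' One record per patient-year in a Markov state, with each cost component
#' drawn from an independent gamma distribution whose mean is the supplied
#' per-state component mean and whose coefficient of variation is `cv`.
#'
#' @param state_means A tibble with columns `state` and one column per cost
#'   component (e.g. `covered`, `noncovered`, `transport`, `time`);
#'   defaults to the base-case per-state annual cost means.
#' @param n_patient_years Patient-years to generate per state.
#' @param seed Integer seed.
#' @param cv Coefficient of variation of each gamma component (default 0.8,
#'   a documented stand-in for unobserved claims dispersion).
#' @return A tibble with columns `patient`, `state`, `year`, and one column
#'   per cost component.
#' @export
synth_claims_episodes <- function(state_means = default_state_cost_means(),
                                  n_patient_years = 1000, seed = 1,
                                  cv = 0.8) {
  if (n_patient_years < 0) stop("n_patient_years must be >= 0", call. = FALSE)
  set.seed(seed)
  comps <- setdiff(names(state_means), "state")
  if (any(as.matrix(state_means[, comps]) < 0))
    stop("cost means must be non-negative", call. = FALSE)
  if (n_patient_years == 0) {
    empty <- tibble::tibble(patient = integer(), state = character(),
                            year = integer())
    for (cmp in comps) empty[[cmp]] <- numeric()
    return(empty)
  }
  purrr::map_dfr(seq_len(nrow(state_means)), function(i) {
    rec <- tibble::tibble(
      patient = seq_len(n_patient_years),
      state = state_means$state[i],
      year = 1L)
    for (cmp in comps) {
      m <- state_means[[cmp]][i]
      if (m == 0) {
        rec[[cmp]] <- rep(0, n_patient_years)
      } else {
        shape <- 1 / cv^2
        rec[[cmp]] <- stats::rgamma(n_patient_years, shape = shape,
                                    rate = shape / m)
      }
    }
    rec
  })
}

#' Base-case per-state annual cost component means
#'
#' @return A tibble: `state` (NPDR, PDR, DME, SVL) by cost component means
#'   taken from the base-case parameter set.
#' @export
default_state_cost_means <- function() {
  plist <- param_values(default_parameters())
  comp <- function(st, what) pv(plist, paste0("cost_", st, "_", what))
  purrr::map_dfr(c("NPDR", "PDR", "DME", "SVL"), function(st) {
    tibble::tibble(state = st,
                   covered = comp(st, "covered"),
                   noncovered = comp(st, "noncovered"),
                   transport = comp(st, "transport"),
                   time = comp(st, "time"))
  })
}

#' Macro-costing estimator
#'
#' Estimates per-state annual cost components from episode records as the
#' total component cost divided by the patient-years observed in the state
#' (cost per state-year, not itemised micro-costing).
#'
#' @param records A tibble from [synth_claims_episodes()] (columns
#'   `patient`, `state`, `year`, cost components).
#' @return A tibble per state: `state`, `patient_years`, and for each cost
#'   component its mean annual cost and standard error (`se_` columns).
#' @export
macro_costing <- function(records) {
  comps <- setdiff(names(records), c("patient", "state", "year"))
  if (nrow(records) == 0)
    stop("no episode records supplied", call. = FALSE)
  dplyr::summarise(
    dplyr::group_by(records, .data$state),
    patient_years = dplyr::n(),
    dplyr::across(dplyr::all_of(comps),
                  list(mean = mean,
                       se = ~ stats::sd(.x) / sqrt(dplyr::n()))),
    .groups = "drop")
}

#' Generate EQ-5D-like utility survey responses
#'
#' Draws one utility value per respondent from a beta distribution with the
#' given per-state mean and standard deviation (method of moments), the
#' survey size split evenly across states.
#'
#' @param state_means A tibble with columns `state` and `utility` (mean
#'   utility per state); defaults to the midrange of the base-case
#'   age-interpolated utilities.
#' @param n Total number of respondents (default 300).
#' @param seed Integer seed.
#' @param sd Per-response standard deviation (default 0.08, a documented
#'   stand-in).
#' @return A tibble: `respondent`, `state`, `utility` (in \[0, 1\]).
#' @export
synth_eq5d_survey <- function(state_means = default_state_utility_means(),
                              n = 300, seed = 1, sd = 0.08) {
  if (any(state_means$utility < 0 | state_means$utility > 1))
    stop("utility means must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  ns <- nrow(state_means)
  per <- diff(round(seq(0, n, length.out = ns + 1)))
  purrr::map_dfr(seq_len(ns), function(i) {
    m <- state_means$utility[i]
    k <- per[i]
    if (k == 0) return(NULL)
    u <- if (sd == 0) rep(m, k) else {
      nu <- m * (1 - m) / sd^2 - 1
      if (nu <= 0) stop("sd too large for beta mean ", m, call. = FALSE)
      stats::rbeta(k, m * nu, (1 - m) * nu)
    }
    tibble::tibble(respondent = seq_len(k), state = state_means$state[i],
                   utility = pmin(1, pmax(0, u)))
  })
}

#' Base-case per-state mean utilities (midrange of the age span)
#'
#' @return A tibble: `state`, `utility` — the state utility at the midpoint
#'   of the age range (age 75).
#' @export
default_state_utility_means <- function() {
  params <- default_parameters()
  purrr::map_dfr(c("NPDR", "PDR", "DME", "SVL"), function(st) {
    tibble::tibble(state = st,
                   utility = age_adjusted_utility(st, 75, params))
  })
}

#' Estimate per-state mean utilities from survey responses
#'
#' @param responses A tibble from [synth_eq5d_survey()].
#' @return A tibble per state: `state`, `n`, `utility` (mean), `se`.
#' @export
estimate_state_utilities <- function(responses) {
  dplyr::summarise(
    dplyr::group_by(responses, .data$state),
    n = dplyr::n(),
    se = stats::sd(.data$utility) / sqrt(dplyr::n()),
    utility = mean(.data$utility),
    .groups = "drop") |>
    dplyr::select("state", "n", "utility", "se")
}
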