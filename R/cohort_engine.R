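# Deterministic cohort simulation and the microsimulation validation oracle.

#' Cohort simulation settings
#'
#' @param start_age Cohort entry age (years). The cohort starts in the PDR
#'   state, first-line therapy pending.
#' @param end_age Simulation stops when the cohort reaches this age; with
#'   the defaults there are 50 annual cycles (ages 50-99 occupied).
#' @param discount_offset Exponent offset for discounting: cycle `t`
#'   rewards are discounted by `(1 + r)^-(t + discount_offset)`. The
#'   default 0 leaves the first cycle undiscounted; set 1 for the
#'   alternative convention. No half-cycle correction is applied; rewards
#'   accrue on the state occupied at cycle start.
#' @param cohort_size Nominal cohort size; results are per-capita, so this
#'   only scales reported totals in exports.
#' @return A list of class `pdr_settings`.
#' @export
cohort_settings <- function(start_age = 50, end_age = 100,
                            discount_offset = 0, cohort_size = 100000) {
  if (start_age < 0 || end_age <= start_age)
    stop("require 0 <= start_age < end_age", call. = FALSE)
  structure(list(start_age = start_age, end_age = end_age,
                 discount_offset = discount_offset,
                 cohort_size = cohort_size),
            class = "pdr_settings")
}

# Fast numeric engine shared by run_cohort, DSA and PSA.
# Returns list(totals = named numeric, occ = n_states x cycles occupancy
# at cycle start, per_cycle = cycles x 4 discounted accruals).
cohort_engine <- function(strategy, plist, lt, settings,
                          space = NULL, M = NULL, keep_trace = FALSE) {
  strategy <- strategy_spec(strategy)
  if (is.null(space)) space <- build_state_space(strategy)
  if (is.null(M)) M <- conditional_matrix(strategy, plist, space)
  cycles <- settings$end_age - settings$start_age
  ages <- settings$start_age + seq_len(cycles) - 1
  n <- nrow(space)
  labels <- space$label
  dead_i <- which(labels == "DEAD")

  q_gen <- baseline_q(lt, ages)
  rr_d <- pv(plist, "rr_death_diabetes")
  rr_s <- pv(plist, "rr_death_SVL")
  is_svl <- space$clinical == "SVL"
  is_dead <- space$clinical == "DEAD"
  # q_age[i, t]: death probability of state i during cycle t
  q_age <- outer(ifelse(is_dead, 0, ifelse(is_svl, rr_d * rr_s, rr_d)),
                 q_gen)
  q_age <- pmin(q_age, 1)  # pmin takes attributes (dims) from its first arg

  start_i <- match(attr(space, "start_label"), labels)
  occ <- numeric(n)
  occ[start_i] <- 1
  OCC <- matrix(0, n, cycles, dimnames = list(labels, NULL))
  for (t in seq_len(cycles)) {
    OCC[, t] <- occ
    qd <- q_age[, t]
    surv <- occ * (1 - qd)
    occ <- as.numeric(crossprod(M, surv))
    occ[dead_i] <- occ[dead_i] + sum(OCC[, t] * qd)
  }

  # rewards: costs are age-invariant except the SVL care cap at age 90
  rw <- reward_matrix(strategy, settings$start_age, plist, space)
  care_vec <- ifelse(is_svl, pv(plist, "cost_SVL_care"), 0)
  societal_no_care <- rw[, "cost_societal"] - care_vec *
    (settings$start_age < 90)
  care_on <- as.numeric(ages < 90)

  # utility: linear decline with age, pVFD disutility, floored at 0
  u0 <- numeric(n)
  for (cl in c("NPDR", "PDR", "DME", "SVL")) {
    sel <- space$clinical == cl
    if (any(sel)) u0[sel] <- pmin(1, pv(plist, paste0("u_", cl)))
  }
  u0 <- u0 - pv(plist, "disutility_pVFD") * space$ever_prp
  u0[is_dead] <- 0
  slope <- pv(plist, "utility_age_span") / 50
  U <- pmax(outer(u0, rep(1, cycles)) -
              outer(rep(1, n), slope * (ages - 50)), 0)
  U[is_dead, ] <- 0

  r <- pv(plist, "discount_rate")
  disc <- (1 + r)^-(seq_len(cycles) - 1 + settings$discount_offset)

  per_payer <- as.numeric(crossprod(OCC, rw[, "cost_payer"]))
  per_health <- as.numeric(crossprod(OCC, rw[, "cost_healthcare"]))
  per_societal <- as.numeric(crossprod(OCC, societal_no_care)) +
    care_on * as.numeric(crossprod(OCC, care_vec))
  per_qaly <- colSums(OCC * U)

  per_cycle <- cbind(cost_payer = per_payer, cost_healthcare = per_health,
                     cost_societal = per_societal, qaly = per_qaly)
  totals <- colSums(disc * per_cycle)
  list(totals = totals,
       occ = if (keep_trace) OCC else NULL,
       per_cycle = if (keep_trace) per_cycle else NULL,
       disc = disc, ages = ages)
}

#' Run the deterministic cohort simulation for one strategy
#'
#' Simulates the Markov cohort over annual cycles from `start_age` until
#' the cohort reaches `end_age`, accruing per-cycle costs (for all three
#' perspectives) and QALYs on the state occupied at cycle start,
#' discounting cycle `t` by `(1 + r)^-t`.
#'
#' @param strategy A strategy name or [strategy_spec()].
#' @param params A `pdr_params` tibble or named value list.
#' @param lt A `pdr_life_table` covering the horizon.
#' @param settings A [cohort_settings()] list.
#' @return A list of class `pdr_cohort` with elements `trace` (a tibble:
#'   `cycle`, `age`, one occupancy column per state, per-perspective
#'   discounted cost and discounted QALY accrued that cycle) and `result`
#'   (a one-row tibble: `strategy`, `cost_payer`, `cost_healthcare`,
#'   `cost_societal`, `qaly` — expected discounted lifetime totals per
#'   patient).
#' @examples
#' \donttest{
#' run <- run_cohort("prp-only", default_parameters(), gompertz_life_table())
#' glance(run)
#' }
#' @export
run_cohort <- function(strategy, params, lt, settings = cohort_settings()) {
  strategy <- strategy_spec(strategy)
  plist <- if (inherits(params, "pdr_params")) param_values(params) else params
  if (settings$end_age - 1 > max(lt$age))
    stop("life table does not cover the simulation horizon", call. = FALSE)
  eng <- cohort_engine(strategy, plist, lt, settings, keep_trace = TRUE)
  occ_t <- t(eng$occ)
  colnames(occ_t) <- rownames(eng$occ)
  trace <- dplyr::bind_cols(
    tibble::tibble(cycle = seq_len(nrow(occ_t)) - 1, age = eng$ages),
    tibble::as_tibble(occ_t),
    tibble::as_tibble(eng$per_cycle * eng$disc) |>
      stats::setNames(c("disc_cost_payer", "disc_cost_healthcare",
                        "disc_cost_societal", "disc_qaly")))
  result <- tibble::tibble(strategy = strategy$name,
                           cost_payer = eng$totals[["cost_payer"]],
                           cost_healthcare = eng$totals[["cost_healthcare"]],
                           cost_societal = eng$totals[["cost_societal"]],
                           qaly = eng$totals[["qaly"]])
  structure(list(trace = trace, result = result, strategy = strategy,
                 settings = settings),
            class = "pdr_cohort")
}

#' @export
print.pdr_cohort <- function(x, ...) {
  cat("Markov cohort run:", x$strategy$name, "\n")
  cat(sprintf("  ages %d-%d, %d annual cycles, discount exponent t + %g, ",
              x$settings$start_age, x$settings$end_age - 1,
              nrow(x$trace), x$settings$discount_offset))
  cat("no half-cycle correction\n")
  print(x$result)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cohort run into its per-cycle trace
#'
#' @param x A `pdr_cohort` object.
#' @param ... Unused.
#' @return The per-cycle trace tibble.
#' @export
tidy.pdr_cohort <- function(x, ...) x$trace

#' One-row summary of a cohort run
#'
#' @param x A `pdr_cohort` object.
#' @param ... Unused.
#' @return A one-row tibble with discounted lifetime cost per perspective
#'   and QALYs.
#' @export
glance.pdr_cohort <- function(x, ...) x$result

#' Plot clinical-state occupancy over the cohort trace
#'
#' @param object A `pdr_cohort` object.
#' @param ... Unused.
#' @return A ggplot object: occupancy by clinical state vs age.
#' @export
autoplot.pdr_cohort <- function(object, ...) {
  space <- build_state_space(object$strategy)
  long <- tidyr::pivot_longer(object$trace,
                              cols = dplyr::all_of(space$label),
                              names_to = "label", values_to = "occupancy")
  long <- dplyr::left_join(long, space[, c("label", "clinical")],
                           by = "label")
  agg <- dplyr::summarise(
    dplyr::group_by(long, .data$age,
                    clinical = factor(.data$clinical,
                                      c("NPDR", "PDR", "DME", "SVL", "DEAD"))),
    occupancy = sum(.data$occupancy), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(.data$age, .data$occupancy,
                                    colour = .data$clinical)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Age (years)", y = "Cohort fraction",
                  colour = "State",
                  title = paste("State occupancy:", object$strategy$name)) +
    ggplot2::theme_minimal()
}

#' Run every strategy under shared parameters
#'
#' @param params A `pdr_params` tibble or named value list.
#' @param lt A `pdr_life_table`.
#' @param settings A [cohort_settings()] list.
#' @param strategies Strategy names (default: all four).
#' @return A tibble with one row per strategy: discounted lifetime
#'   `cost_payer`, `cost_healthcare`, `cost_societal`, and `qaly`.
#' @export
run_all_strategies <- function(params, lt, settings = cohort_settings(),
                               strategies = pdr_strategies()) {
  plist <- if (inherits(params, "pdr_params")) param_values(params) else params
  purrr::map_dfr(strategies, function(s) {
    eng <- cohort_engine(strategy_spec(s), plist, lt, settings)
    tibble::tibble(strategy = gsub("_", "-", tolower(s)),
                   cost_payer = eng$totals[["cost_payer"]],
                   cost_healthcare = eng$totals[["cost_healthcare"]],
                   cost_societal = eng$totals[["cost_societal"]],
                   qaly = eng$totals[["qaly"]])
  })
}

#' Microsimulation oracle for the cohort engine
#'
#' Simulates `n` individual patient trajectories through the same
#' transition probabilities and rewards as the cohort engine and returns
#' Monte-Carlo estimates of expected discounted cost and QALYs with
#' standard errors. Used to validate the deterministic cohort trace: the
#' two must agree within Monte-Carlo error.
#'
#' @param strategy A strategy name or [strategy_spec()].
#' @param params A `pdr_params` tibble or named value list.
#' @param lt A `pdr_life_table`.
#' @param n Number of simulated individuals.
#' @param seed Integer seed.
#' @param settings A [cohort_settings()] list.
#' @return A one-row tibble: strategy, mean discounted cost per perspective
#'   and QALYs, each with a Monte-Carlo standard error (`se_` columns).
#' @export
microsim_oracle <- function(strategy, params, lt, n = 50000, seed = 1,
                            settings = cohort_settings()) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  strategy <- strategy_spec(strategy)
  plist <- if (inherits(params, "pdr_params")) param_values(params) else params
  set.seed(seed)
  space <- build_state_space(strategy)
  M <- conditional_matrix(strategy, plist, space)
  cycles <- settings$end_age - settings$start_age
  ages <- settings$start_age + seq_len(cycles) - 1
  labels <- space$label
  ns <- length(labels)
  dead_i <- which(labels == "DEAD")
  r <- pv(plist, "discount_rate")
  disc <- (1 + r)^-(seq_len(cycles) - 1 + settings$discount_offset)

  # per-age reward vectors (costs vary only through the care cap)
  rw <- reward_matrix(strategy, settings$start_age, plist, space)
  care_vec <- ifelse(space$clinical == "SVL", pv(plist, "cost_SVL_care"), 0)
  societal_no_care <- rw[, "cost_societal"] - care_vec *
    (settings$start_age < 90)

  state <- rep(match(attr(space, "start_label"), labels), n)
  tot <- matrix(0, n, 4,
                dimnames = list(NULL, c("cost_payer", "cost_healthcare",
                                        "cost_societal", "qaly")))
  alive <- rep(TRUE, n)
  for (t in seq_len(cycles)) {
    age <- ages[t]
    u_age <- numeric(ns)
    for (cl in c("NPDR", "PDR", "DME", "SVL")) {
      sel <- space$clinical == cl
      if (any(sel))
        u_age[sel] <- pmax(0, age_adjusted_utility(cl, age, plist) -
                              pv(plist, "disutility_pVFD") *
                              space$ever_prp[sel])
    }
    soc <- societal_no_care + care_vec * (age < 90)
    idx_alive <- which(alive)
    s_al <- state[idx_alive]
    tot[idx_alive, "cost_payer"] <- tot[idx_alive, "cost_payer"] +
      disc[t] * rw[s_al, "cost_payer"]
    tot[idx_alive, "cost_healthcare"] <- tot[idx_alive, "cost_healthcare"] +
      disc[t] * rw[s_al, "cost_healthcare"]
    tot[idx_alive, "cost_societal"] <- tot[idx_alive, "cost_societal"] +
      disc[t] * soc[s_al]
    tot[idx_alive, "qaly"] <- tot[idx_alive, "qaly"] + disc[t] * u_age[s_al]

    Tm <- compose_mortality(M, death_prob_by_state(space, age, plist, lt),
                            labels)
    for (s in unique(s_al)) {
      members <- idx_alive[s_al == s]
      state[members] <- sample.int(ns, length(members), replace = TRUE,
                                   prob = Tm[s, ])
    }
    alive <- state != dead_i
  }
  est <- colMeans(tot)
  se <- apply(tot, 2, stats::sd) / sqrt(n)
  tibble::tibble(strategy = strategy$name, n = n,
                 cost_payer = est[["cost_payer"]],
                 se_cost_payer = se[["cost_payer"]],
                 cost_healthcare = est[["cost_healthcare"]],
                 se_cost_healthcare = se[["cost_healthcare"]],
                 cost_societal = est[["cost_societal"]],
                 se_cost_societal = se[["cost_societal"]],
                 qaly = est[["qaly"]], se_qaly = se[["qaly"]])
}
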