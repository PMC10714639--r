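# Per-cycle transition matrices and state rewards.

# Survivor-conditional transition matrix over the strategy's state space.
# Age-independent: mortality is composed in afterwards, so the expensive
# structure is built once per (strategy, parameter set).
conditional_matrix <- function(strategy, plist, space = NULL) {
  strategy <- strategy_spec(strategy)
  if (is.null(space)) space <- build_state_space(strategy)
  labels <- space$label
  n <- length(labels)
  M <- matrix(0, n, n, dimnames = list(labels, labels))
  states <- space_states(space)
  for (i in seq_len(n)) {
    succ <- survivor_successors(states[[i]], strategy, plist)
    j <- match(names(succ), labels)
    if (anyNA(j))
      stop("successor outside the state space: ",
           paste(names(succ)[is.na(j)], collapse = ", "), call. = FALSE)
    M[i, j] <- succ
    rs <- sum(succ)
    if (abs(rs - 1) > 1e-12)
      stop("survivor-conditional row for ", labels[i],
           " sums to ", format(rs), call. = FALSE)
  }
  M
}

#' Per-cycle transition matrix
#'
#' Builds the row-stochastic one-cycle transition matrix for a strategy at
#' a given age. Death is applied first through [state_death_prob()] (with
#' the SVL relative risk for SVL occupants); among survivors, PDR occupants
#' are treated with the current line's therapy with probability
#' `1 - p_loss_followup`, successful treatment moves them to NPDR
#' (recording the therapy), failed or untreated occupants face the SVL and
#' DME transition risks, NPDR occupants face therapy-specific recurrence
#' and DME risk, DME resolves back to its origin state with the anti-VEGF
#' DME success probability, endophthalmitis adds a small per-injection SVL
#' risk for injection-receiving occupants, and SVL is absorbing (except
#' death) with tenure advancing annually.
#'
#' @param strategy A strategy name or [strategy_spec()].
#' @param age Age (years) at the start of the cycle; must be covered by the
#'   life table.
#' @param params A `pdr_params` tibble or named value list.
#' @param lt A `pdr_life_table`.
#' @return A named row-stochastic matrix over [build_state_space()] rows
#'   (each row sums to 1 within 1e-12).
#' @export
transition_matrix <- function(strategy, age, params, lt) {
  strategy <- strategy_spec(strategy)
  plist <- if (inherits(params, "pdr_params")) param_values(params) else params
  space <- build_state_space(strategy)
  M <- conditional_matrix(strategy, plist, space)
  q <- death_prob_by_state(space, age, plist, lt)
  compose_mortality(M, q, space$label)
}

# q(state) at one age
death_prob_by_state <- function(space, age, plist, lt) {
  q_gen <- baseline_q(lt, age)
  q <- state_death_prob(rep(q_gen, nrow(space)), plist,
                        is_svl = space$clinical == "SVL")
  q[space$clinical == "DEAD"] <- 0
  q
}

# full matrix = death first, then survivor-conditional transitions
compose_mortality <- function(M, q, labels) {
  Tm <- (1 - q) * M
  Tm[, labels == "DEAD"] <- Tm[, labels == "DEAD"] + q
  Tm
}

#' Age-adjusted health-state utility
#'
#' Utilities decline linearly with age across the state's published range:
#' the upper bound applies at age 50 and the lower bound (upper minus
#' `utility_age_span`) at age 100. Sampled utilities above 1 are censored
#' to 1 before interpolation.
#'
#' @param state Clinical state: `"NPDR"`, `"PDR"`, `"DME"`, or `"SVL"`.
#' @param age Age in years, in \[50, 100\] (vectorised).
#' @param params A `pdr_params` tibble or named value list.
#' @return Utility value(s) in \[0, 1\].
#' @examples
#' age_adjusted_utility("NPDR", 50, default_parameters())   # 0.904
#' age_adjusted_utility("NPDR", 100, default_parameters())  # 0.849
#' @export
age_adjusted_utility <- function(state, age, params) {
  plist <- if (inherits(params, "pdr_params")) param_values(params) else params
  if (any(age < 50 | age > 100))
    stop("age must lie in [50, 100]", call. = FALSE)
  u50 <- pmin(1, pv(plist, paste0("u_", state)))
  span <- pv(plist, "utility_age_span")
  pmax(0, pmin(1, u50 - span * (age - 50) / 50))
}

svl_continuation <- function(plist, tenure) {
  nm <- paste0("svl_continuation_y", sub("5plus", "5plus", tenure))
  min(1, pv(plist, nm))
}

#' Per-state, per-cycle costs and utilities
#'
#' Annual state costs (medical covered / non-covered, transportation, time,
#' and for SVL care and low-vision glasses) plus expected treatment costs:
#' PDR occupants treated with PRP accrue one PRP episode and those treated
#' with anti-VEGF three injection episodes (both scaled by the
#' `1 - p_loss_followup` treated fraction); DME occupants accrue three
#' injection episodes; SVL occupants accrue two injections scaled by the
#' tenure-year continuation probability. Expected endophthalmitis treatment
#' cost is injections x per-injection incidence x episode cost. Care cost
#' accrues in SVL only while age < 90. The utility column is the
#' age-adjusted state utility minus the permanent pVFD disutility for
#' post-PRP states, floored at 0.
#'
#' Perspectives: payer = covered medical; healthcare = covered +
#' non-covered medical; societal = healthcare + transportation + time +
#' care + low-vision glasses.
#'
#' @param strategy A strategy name or [strategy_spec()].
#' @param age Age in years at the start of the cycle.
#' @param params A `pdr_params` tibble or named value list.
#' @return A tibble with one row per model state: `label`, `cost_payer`,
#'   `cost_healthcare`, `cost_societal`, `utility`.
#' @export
cycle_rewards <- function(strategy, age, params) {
  strategy <- strategy_spec(strategy)
  plist <- if (inherits(params, "pdr_params")) param_values(params) else params
  space <- build_state_space(strategy)
  rw <- reward_matrix(strategy, age, plist, space)
  tibble::tibble(label = space$label,
                 cost_payer = rw[, "cost_payer"],
                 cost_healthcare = rw[, "cost_healthcare"],
                 cost_societal = rw[, "cost_societal"],
                 utility = rw[, "utility"])
}

# numeric reward matrix (n_states x 4), the engine-facing form
reward_matrix <- function(strategy, age, plist, space) {
  n <- nrow(space)
  comp <- function(stub, what) pv(plist, paste0("cost_", stub, "_", what))
  # annual state cost components by clinical state
  state_comp <- function(what) {
    v <- numeric(n)
    for (cl in c("NPDR", "PDR", "DME", "SVL")) {
      v[space$clinical == cl] <- comp(cl, what)
    }
    v
  }
  covered <- state_comp("covered")
  noncov <- state_comp("noncovered")
  transport <- state_comp("transport")
  timec <- state_comp("time")
  care <- ifelse(space$clinical == "SVL" & age < 90,
                 pv(plist, "cost_SVL_care"), 0)
  glasses <- ifelse(space$clinical == "SVL", pv(plist, "cost_SVL_glasses"), 0)

  # expected treatment episodes per occupant
  treated <- 1 - pv(plist, "p_loss_followup")
  prp_n <- numeric(n)
  inj_n <- numeric(n)
  for (i in seq_len(n)) {
    cl <- space$clinical[i]
    if (cl == "PDR") {
      therapy <- if (space$line[i] == "first") strategy$first
                 else strategy$second
      if (therapy == "PRP") prp_n[i] <- treated
      else inj_n[i] <- 3 * treated
    } else if (cl == "DME") {
      inj_n[i] <- 3
    } else if (cl == "SVL") {
      inj_n[i] <- 2 * svl_continuation(plist, space$svl_tenure[i])
    }
  }
  endo_n <- inj_n * pv(plist, "p_endoph_per_injection")
  ep <- function(what) {
    prp_n * comp("PRP", what) + inj_n * comp("antiVEGF", what) +
      endo_n * comp("endoph", what)
  }
  covered <- covered + ep("covered")
  noncov <- noncov + ep("noncovered")
  transport <- transport + ep("transport")
  timec <- timec + ep("time")

  cost_payer <- covered
  cost_healthcare <- covered + noncov
  cost_societal <- cost_healthcare + transport + timec + care + glasses

  utility <- numeric(n)
  dis <- pv(plist, "disutility_pVFD")
  for (cl in c("NPDR", "PDR", "DME", "SVL")) {
    sel <- space$clinical == cl
    if (any(sel)) {
      u <- age_adjusted_utility(cl, age, plist)
      utility[sel] <- pmax(0, u - dis * space$ever_prp[sel])
    }
  }
  cbind(cost_payer = cost_payer, cost_healthcare = cost_healthcare,
        cost_societal = cost_societal, utility = utility)
}
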