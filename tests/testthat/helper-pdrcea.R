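# Shared fixtures and independent oracles for the test suite.

base_lt <- gompertz_life_table()
base_params <- default_parameters()

# zero-mortality life table (Gompertz a -> 0 limit)
zero_lt <- gompertz_life_table(a = 0)

# A random valid parameter set: every ranged parameter drawn uniformly
# within its sensitivity bounds (capped at 1 for probabilities/utilities),
# which preserves all type invariants by construction.
random_valid_params <- function(seed) {
  set.seed(seed)
  p <- base_params
  ranged <- which(p$low < p$high)
  for (i in ranged) {
    hi <- p$high[i]
    if (p$units[i] %in% c("probability", "utility")) hi <- min(hi, 1)
    p$value[i] <- stats::runif(1, p$low[i], hi)
  }
  validate_parameters(p)
  p
}

# Degenerate parameters: no treatment delivered (full loss to follow-up)
# and no disease transitions, so a cohort starting in PDR stays there
# (with zero_lt this gives an identity chain outside the SVL tunnel).
frozen_disease_params <- function(params = base_params) {
  set_parameters(params,
                 p_NPDR_to_DME = 0, p_PDR_to_DME = 0, p_PDR_to_SVL = 0,
                 p_PRP_success = 0, p_recur_post_PRP = 0,
                 p_antiVEGF_DME_success = 0,
                 p_endoph_per_injection = 0, p_loss_followup = 1)
}

# Strategy-symmetry conditions: equal effectiveness and recurrence across
# therapies, per-cycle treatment costs equalised (one PRP episode vs three
# injections), no pVFD disutility, no endophthalmitis.
symmetric_params <- function(params = base_params) {
  plist <- param_values(params)
  set_parameters(params,
                 rr_antiVEGF_vs_PRP_effect = 1, rr_recur_antiVEGF_vs_PRP = 1,
                 disutility_pVFD = 0, p_endoph_per_injection = 0,
                 cost_antiVEGF_covered = plist$cost_PRP_covered / 3,
                 cost_antiVEGF_noncovered = plist$cost_PRP_noncovered / 3,
                 cost_antiVEGF_transport = plist$cost_PRP_transport / 3,
                 cost_antiVEGF_time = plist$cost_PRP_time / 3)
}

# Brute-force efficiency-frontier oracle: a strategy is on the frontier iff
# it attains the maximal net monetary benefit for some willingness to pay
# (candidate WTPs: 0, every pairwise positive ICER and midpoints between
# consecutive candidates, and a value beyond the largest).
frontier_oracle <- function(tbl) {
  n <- nrow(tbl)
  icers <- c()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dq <- tbl$qaly[j] - tbl$qaly[i]
      dc <- tbl$cost[j] - tbl$cost[i]
      if (dq != 0 && dc / dq > 0) icers <- c(icers, dc / dq)
    }
  }
  lam <- sort(unique(c(0, icers)))
  lam <- sort(unique(c(lam, (utils::head(lam, -1) + utils::tail(lam, -1)) / 2,
                       max(lam) + 1)))
  on_frontier <- rep(FALSE, n)
  for (w in lam) {
    b <- w * tbl$qaly - tbl$cost
    on_frontier[b >= max(b) - 1e-9] <- TRUE
  }
  tbl$strategy[on_frontier]
}

# random strategy instances for frontier tests
random_frontier_instance <- function(k) {
  tibble::tibble(strategy = paste0("s", seq_len(k)),
                 cost_healthcare = stats::runif(k, 1000, 50000),
                 qaly = stats::runif(k, 5, 15))
}
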