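test_that("each strategy reaches only its legal state subset", {
  sp_prp <- build_state_space("prp-only")
  expect_false(any(sp_prp$line == "second", na.rm = TRUE))

  sp_av <- build_state_space("antivegf-only")
  expect_false(any(sp_av$ever_prp))
  expect_false(any(sp_av$line == "second", na.rm = TRUE))

  # two-line strategies do reach a second line
  expect_true(any(build_state_space("prp-first")$line == "second",
                  na.rm = TRUE))
  expect_true(any(build_state_space("antivegf-first")$line == "second",
                  na.rm = TRUE))

  # six SVL tenure tunnel states per reachable pVFD flag value
  for (s in pdr_strategies()) {
    sp <- build_state_space(s)
    svl <- sp[sp$clinical == "SVL", ]
    counts <- table(svl$ever_prp)
    expect_true(all(counts == 6), label = s)
    expect_setequal(unique(svl$svl_tenure),
                    c("1", "2", "3", "4", "5", "5plus"))
  }

  # DEAD present exactly once, and start state is first-line PDR
  sp <- build_state_space("prp-first")
  expect_equal(sum(sp$clinical == "DEAD"), 1)
  expect_equal(attr(sp, "start_label"), "PDR|first|novfd")
})

test_that("PDR therapy success/recurrence follow the relative-risk rules", {
  expect_equal(unname(pdr_treatment_probs("PRP", base_params)),
               c(0.2008, 0.0169))
  expect_equal(unname(pdr_treatment_probs("antiVEGF", base_params)),
               c(0.2008 * 1.75, 0.0169 * 1.15))
  p1 <- set_parameters(base_params, rr_antiVEGF_vs_PRP_effect = 1,
                       rr_recur_antiVEGF_vs_PRP = 1)
  expect_equal(pdr_treatment_probs("antiVEGF", p1),
               pdr_treatment_probs("PRP", p1))
  expect_error(pdr_treatment_probs("laser", base_params), "therapy")
})

test_that("transition matrix rows compose death, treatment, and progression", {
  Tm <- transition_matrix("prp-only", 60, base_params, base_lt)
  expect_true(all(abs(rowSums(Tm) - 1) < 1e-12))
  expect_true(all(Tm >= 0))

  # absorbing death
  expect_equal(unname(Tm["DEAD", "DEAD"]), 1)
  expect_equal(sum(Tm["DEAD", ]), 1)

  # hand-computed first-line PDR row: survive, be treated (0.8), succeed
  q <- min(1, base_lt$q[base_lt$age == 60] * 1.49)
  expect_equal(unname(Tm["PDR|first|novfd", "NPDR|first|PRP|pvfd"]),
               (1 - q) * 0.8 * 0.2008, tolerance = 1e-12)
  # untreated and failed-treated occupants face the SVL risk
  expect_equal(unname(Tm["PDR|first|novfd", "SVL|t1|novfd"]),
               (1 - q) * 0.2 * 0.18, tolerance = 1e-12)
  expect_equal(unname(Tm["PDR|first|novfd", "SVL|t1|pvfd"]),
               (1 - q) * 0.8 * (1 - 0.2008) * 0.18, tolerance = 1e-12)
  expect_equal(unname(Tm["PDR|first|novfd", "DEAD"]), q, tolerance = 1e-12)

  # SVL tunnel advances and saturates
  expect_equal(unname(Tm["SVL|t2|novfd", "SVL|t3|novfd"]), 1 -
    min(1, base_lt$q[base_lt$age == 60] * 1.49 * 11.54), tolerance = 1e-12)
  expect_gt(Tm["SVL|t5plus|novfd", "SVL|t5plus|novfd"], 0)

  # frozen disease + zero mortality: every clinical state holds its
  # occupants (only the SVL tenure clock, which is structural, advances)
  Ti <- transition_matrix("prp-only", 60, frozen_disease_params(), zero_lt)
  sp <- build_state_space("prp-only")
  non_svl <- sp$clinical != "SVL"
  expect_equal(unname(Ti[non_svl, non_svl]), diag(sum(non_svl)),
               tolerance = 1e-14)
  expect_equal(unname(Ti["SVL|t1|novfd", "SVL|t2|novfd"]), 1)
  expect_equal(unname(Ti["SVL|t5plus|pvfd", "SVL|t5plus|pvfd"]), 1)
})

test_that("row-stochasticity holds across strategies, ages, random params", {
  for (seed in 1:25) {
    p <- random_valid_params(seed)
    for (s in pdr_strategies()) {
      for (age in c(50, 75, 99)) {
        Tm <- transition_matrix(s, age, p, base_lt)
        expect_true(all(abs(rowSums(Tm) - 1) < 1e-12))
        expect_true(all(Tm >= 0))
      }
    }
  }
})

test_that("inconsistent probability overrides are rejected, not normalised", {
  bad <- set_parameters(base_params, p_PDR_to_SVL = 0.9, p_PDR_to_DME = 0.9)
  expect_error(transition_matrix("prp-only", 60, bad, base_lt), "exceeds 1")
})

test_that("cycle rewards reproduce the published state costs and caps", {
  rw <- cycle_rewards("prp-only", 50, base_params)
  sp <- build_state_space("prp-only")

  npdr <- rw[grepl("^NPDR", rw$label), ]
  expect_true(all(abs(npdr$cost_healthcare - 172) < 1e-12))
  expect_true(all(abs(npdr$cost_payer - 160) < 1e-12))

  # SVL societal cost: care accrues at 89 but not at 91; the tenure-year
  # continuation probability scales only the injection component
  rw89 <- cycle_rewards("prp-only", 89, base_params)
  rw91 <- cycle_rewards("prp-only", 91, base_params)
  svl3 <- "SVL|t3|novfd"
  d_care <- rw89$cost_societal[rw89$label == svl3] -
    rw91$cost_societal[rw91$label == svl3]
  expect_equal(d_care, 11826)
  # payer cost of tenure-3 SVL: state cost + 2 injections at 65% continuation
  expect_equal(rw89$cost_payer[rw89$label == svl3],
               338 + 2 * 0.65 * 447 * (1 + 0.0006 * 2143 / 447),
               tolerance = 1e-9)

  # permanent pVFD disutility
  u_cols <- rw[rw$label %in% c("PDR|first|novfd", "PDR|first|pvfd"), ]
  expect_equal(u_cols$utility[u_cols$label == "PDR|first|novfd"] -
                 u_cols$utility[u_cols$label == "PDR|first|pvfd"], 0.01)

  # perspective nesting
  expect_true(all(rw$cost_societal >= rw$cost_healthcare - 1e-12))
  expect_true(all(rw$cost_healthcare >= rw$cost_payer - 1e-12))
  expect_true(all(rw$utility >= 0 & rw$utility <= 1))
})

test_that("utilities interpolate linearly from age 50 to age 100", {
  expect_equal(age_adjusted_utility("NPDR", 50, base_params), 0.904)
  expect_equal(age_adjusted_utility("NPDR", 100, base_params), 0.849)
  expect_equal(age_adjusted_utility("NPDR", 75, base_params), 0.8765)
  expect_equal(age_adjusted_utility("SVL", 100, base_params), 0.796)
  expect_error(age_adjusted_utility("NPDR", 40, base_params), "\\[50, 100\\]")
})

test_that("with symmetric therapies all four strategies coincide", {
  sym <- symmetric_params()
  res <- run_all_strategies(sym, base_lt)
  for (col in c("cost_payer", "cost_healthcare", "cost_societal", "qaly")) {
    expect_equal(max(res[[col]]) - min(res[[col]]), 0, tolerance = 1e-9)
  }
})

test_that("raising the PDR-to-SVL risk never lowers lifetime SVL exposure", {
  # equal mortality in and out of SVL isolates the occupancy effect
  for (seed in 1:5) {
    p0 <- set_parameters(random_valid_params(seed), rr_death_SVL = 1)
    p1 <- set_parameters(p0, p_PDR_to_SVL =
                           min(1, param_values(p0)$p_PDR_to_SVL * 1.2))
    for (s in c("prp-only", "antivegf-first")) {
      sp <- build_state_space(s)
      svl_years <- function(p) {
        tr <- run_cohort(s, p, base_lt)$trace
        sum(tr[, sp$label[sp$clinical == "SVL"]])
      }
      expect_gte(svl_years(p1), svl_years(p0) - 1e-10)
    }
  }
})
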