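# Deterministic one-way analysis and the PSA/CEAC machinery. Tornado runs
# here use the full model, so the suite keeps them to targeted parameters.

test_that("one-way bounds move the ICER in the clinically expected way", {
  base_icer <- pdrcea:::pairwise_icer(base_params, "antivegf-only",
                                      "prp-only", "healthcare", base_lt)
  # greater anti-VEGF effectiveness lowers the ICER
  eff <- one_way("rr_antiVEGF_vs_PRP_effect", params = base_params,
                 lt = base_lt, .base_icer = base_icer)
  expect_equal(eff$low, 1.12)   # CI bounds, not ±20%
  expect_equal(eff$high, 2.75)
  expect_lt(eff$icer_high, eff$icer_low)
  expect_equal(eff$icer_base, base_icer, tolerance = 1e-12)

  # a larger PRP visual-field-defect disutility favours anti-VEGF
  dis <- one_way("disutility_pVFD", params = base_params, lt = base_lt,
                 .base_icer = base_icer)
  expect_lt(dis$icer_high, dis$icer_low)

  # an unranged parameter has zero swing
  fixed <- one_way("wtp_threshold", params = base_params, lt = base_lt,
                   .base_icer = base_icer)
  expect_equal(fixed$swing, 0)
  expect_error(one_way("no_such_parameter", params = base_params,
                       lt = base_lt), "unknown")
})

test_that("costs of states a strategy never reaches cannot move its result", {
  # the anti-VEGF-only cohort has no post-PRP states: PRP episode costs and
  # the pVFD disutility are unreachable inputs for it
  res0 <- run_all_strategies(base_params, base_lt,
                             strategies = "antivegf-only")
  for (nm in c("cost_PRP_covered", "cost_PRP_time", "disutility_pVFD")) {
    res1 <- run_all_strategies(at_bound(base_params, nm, "high"), base_lt,
                               strategies = "antivegf-only")
    expect_equal(res1, res0, tolerance = 1e-12, label = nm)
  }
})

test_that("tornado covers every ranged parameter, sorted by swing", {
  # restricted model (few cycles) keeps the full-tornado run light
  sett <- cohort_settings(end_age = 60)
  tor <- tornado(params = base_params, lt = base_lt, settings = sett)
  expect_equal(nrow(tor), sum(base_params$low < base_params$high))
  expect_true(all(diff(tor$swing) <= 1e-9))
  # every row's base evaluation is the single base-case ICER
  expect_equal(max(tor$icer_base) - min(tor$icer_base), 0, tolerance = 1e-9)
  expect_s3_class(autoplot(tor), "ggplot")
})

test_that("PSA output is reproducible and shaped per draw and strategy", {
  p1 <- psa_run(25, seed = 9, lt = base_lt)
  p2 <- psa_run(25, seed = 9, lt = base_lt)
  expect_identical(p1$draws, p2$draws)
  expect_equal(nrow(p1$draws), 25 * 4)

  single <- psa_run(1, seed = 3, lt = base_lt, strategies = "prp-only")
  expect_equal(nrow(single$draws), 1)
  expect_error(psa_run(0), ">= 1")

  # PSA means stay near the base case (mild nonlinearity expected)
  g <- glance(p1)
  base <- run_all_strategies(base_params, base_lt)
  for (s in base$strategy) {
    expect_lt(abs(g$qaly_mean[g$strategy == s] -
                    base$qaly[base$strategy == s]),
              3 * g$qaly_se[g$strategy == s] + 0.05 * base$qaly[1])
  }
  expect_identical(tidy(p1), p1$draws)
})

test_that("CEAC probabilities normalise, split ties, and handle edge cases", {
  psa <- psa_run(40, seed = 21, lt = base_lt)
  cv <- ceac(psa, wtp_grid = seq(0, 100000, 5000))
  sums <- tapply(cv$probability, cv$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(cv$probability >= 0 & cv$probability <= 1))

  # single strategy: probability one everywhere
  solo <- psa_run(5, seed = 2, lt = base_lt, strategies = "prp-only")
  cs <- ceac(solo, wtp_grid = c(0, 10000))
  expect_true(all(cs$probability == 1))

  # exact ties split equally
  tied <- tibble::tibble(draw = c(1, 1), strategy = c("a", "b"),
                         cost_healthcare = c(100, 100), qaly = c(1, 1))
  ct <- ceac(tied, wtp_grid = 5000)
  expect_equal(ct$probability, c(0.5, 0.5))
  expect_error(ceac(tied[0, ], wtp_grid = 0), "empty")
  expect_s3_class(autoplot(cv), "ggplot")
})

test_that("CEAC is monotone for a strategy dominant on effectiveness", {
  # constructed draws where strategy b has the strictly largest QALY always
  set.seed(8)
  k <- 200
  draws <- dplyr::bind_rows(
    tibble::tibble(draw = 1:k, strategy = "a",
                   cost_healthcare = stats::runif(k, 100, 200),
                   qaly = stats::runif(k, 1, 2)),
    tibble::tibble(draw = 1:k, strategy = "b",
                   cost_healthcare = stats::runif(k, 150, 400),
                   qaly = stats::runif(k, 2.5, 3)))
  cv <- ceac(draws, wtp_grid = seq(0, 2000, 50))
  pb <- cv$probability[cv$strategy == "b"]
  expect_true(all(diff(pb) >= 0))
})

test_that("threshold WTP finds and interpolates CEAC crossings", {
  curve <- function(pa, pb, wtp = seq(0, 4000, 1000)) {
    structure(dplyr::bind_rows(
      tibble::tibble(wtp = wtp, strategy = "a", probability = pa),
      tibble::tibble(wtp = wtp, strategy = "b", probability = pb)),
      class = c("pdr_ceac", "tbl_df", "tbl", "data.frame"))
  }
  # never crosses
  expect_true(is.na(threshold_wtp(curve(c(.9, .8, .7, .6, .6),
                                        c(.1, .2, .3, .4, .4)), "a", "b")))
  # crossing exactly at a grid point (equality then strictly above)
  cv <- curve(c(.9, .6, .5, .3, .2), c(.1, .4, .5, .7, .8))
  expect_equal(threshold_wtp(cv, "a", "b"), 2000)
  # analytic linear crossing: d goes -0.2 -> +0.2 between 1000 and 2000
  cv <- curve(c(.9, .6, .4, .3, .2), c(.1, .4, .6, .7, .8))
  expect_equal(threshold_wtp(cv, "a", "b"), 1500)
  expect_error(threshold_wtp(cv, "a", "zzz"), "present")
})
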