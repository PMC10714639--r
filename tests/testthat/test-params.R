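test_that("base-case parameter set matches the published table", {
  plist <- param_values(base_params)
  expect_equal(plist$p_PRP_success, 0.2008)
  expect_equal(plist$discount_rate, 0.045)
  expect_equal(plist$cost_DME_covered, 1732)
  expect_equal(plist$p_NPDR_to_DME, 0.1522)
  expect_equal(plist$rr_antiVEGF_vs_PRP_effect, 1.75)
  expect_equal(plist$rr_death_SVL, 11.54)
  expect_equal(plist$u_NPDR, 0.904)
  expect_equal(plist$u_SVL, 0.851)
  expect_equal(plist$svl_continuation_y3, 0.65)
  expect_equal(plist$wtp_threshold, 24400)
  expect_silent(validate_parameters(base_params))
  # every parameter the engine consumes is present exactly once
  expect_false(any(duplicated(base_params$name)))
})

test_that("parameter files: overrides, rejection of invalid values, defaults", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("p_PRP_success: 0.3", f)
  p <- load_parameters(f)
  expect_equal(param_values(p)$p_PRP_success, 0.3)

  writeLines("p_PRP_success: 1.3", f)
  expect_error(load_parameters(f), "p_PRP_success")

  writeLines("nonsense_key: 1", f)
  expect_error(load_parameters(f), "nonsense_key")

  writeLines("", f)
  expect_equal(param_values(load_parameters(f, fill_defaults = TRUE)),
               param_values(default_parameters()))
  expect_error(load_parameters(f, fill_defaults = FALSE), "missing")

  # distributions block overrides the PSA family metadata
  writeLines(c("distributions:",
               "  rr_death_SVL:",
               "    ci: [9.0, 14.5]"), f)
  p <- load_parameters(f)
  expect_equal(p$ci_lo[p$name == "rr_death_SVL"], 9.0)
})

test_that("sampler construction follows the stated moment rules", {
  get_row <- function(nm) base_params[base_params$name == nm, ]

  ln <- build_sampler(get_row("rr_antiVEGF_vs_PRP_effect"))
  expect_equal(ln$meanlog, 0.5596157879, tolerance = 1e-8)
  expect_equal(ln$sdlog, 0.2291510782, tolerance = 1e-8)

  be <- build_sampler(get_row("p_antiVEGF_DME_success"))
  expect_equal(be$shape1, 44.22064, tolerance = 1e-5)
  expect_equal(be$shape2, 38.58955, tolerance = 1e-5)

  tri <- build_sampler(get_row("p_PDR_to_SVL"))
  expect_equal(tri$mode, 0.18)
  set.seed(42)
  expect_equal(mean(tri$draw(200000)), 0.18, tolerance = 0.003)

  fx <- build_sampler(get_row("discount_rate"))
  expect_equal(fx$draw(5), rep(0.045, 5))

  bad <- get_row("rr_death_SVL")
  bad$base <- -1
  expect_error(build_sampler(bad), "positive")
})

test_that("method-of-moments samplers reproduce their construction moments", {
  set.seed(7)
  for (nm in c("p_PRP_success", "cost_DME_covered")) {
    row <- base_params[base_params$name == nm, ]
    x <- build_sampler(row)$draw(100000)
    se <- 0.2 * row$base / 1.96
    expect_equal(mean(x), row$base, tolerance = 0.02)
    expect_equal(stats::sd(x), se, tolerance = 0.02)
  }
  # lognormal CI endpoints recovered as empirical percentiles (5% relative)
  row <- base_params[base_params$name == "rr_antiVEGF_vs_PRP_effect", ]
  x <- build_sampler(row)$draw(100000)
  q <- stats::quantile(x, c(0.025, 0.975))
  expect_equal(unname(q[1]), 1.12, tolerance = 0.05)
  expect_equal(unname(q[2]), 2.75, tolerance = 0.05)
})

test_that("joint PSA draws are reproducible and respect parameter domains", {
  d1 <- sample_parameter_set(base_params, seed = 123)
  d2 <- sample_parameter_set(base_params, seed = 123)
  expect_identical(d1$value, d2$value)
  expect_equal(attr(d1, "provenance"), "psa-draw")

  # fixed-family parameters never move
  fixed <- base_params$name[base_params$dist == "fixed"]
  expect_equal(d1$value[match(fixed, d1$name)],
               base_params$value[match(fixed, base_params$name)])

  # domain invariants over many joint draws
  set.seed(99)
  draws <- replicate(400, sample_parameter_set(base_params)$value)
  units <- base_params$units
  expect_true(all(draws[units == "probability", ] >= 0 &
                    draws[units == "probability", ] <= 1))
  expect_true(all(draws[units == "USD", ] >= 0))
  expect_true(all(draws[units == "relative_risk", ] > 0))
  expect_true(all(draws[units == "utility", ] <= 1))

  # marginal mean of a beta-sampled probability stays on target
  i <- which(base_params$name == "p_PRP_success")
  se_mean <- stats::sd(draws[i, ]) / sqrt(ncol(draws))
  expect_lt(abs(mean(draws[i, ]) - 0.2008), 3 * se_mean)
})

test_that("utility draws above 1 are censored, not rejected", {
  row <- base_params[base_params$name == "u_DME", ]
  expect_gt(row$high, 1)  # triangle support reaches past 1
  set.seed(5)
  vals <- replicate(3000, draw_one_util <- {
    s <- build_sampler(row)
    pdrcea:::draw_one(s, "utility")
  })
  expect_true(all(vals <= 1))
  expect_gt(mean(vals == 1), 0)  # censoring mass actually occurs
})

test_that("set_parameters validates overrides and rejects unknown names", {
  p <- set_parameters(base_params, p_PRP_success = 0.5)
  expect_equal(param_values(p)$p_PRP_success, 0.5)
  expect_error(set_parameters(base_params, p_PRP_success = 1.5), "probability")
  expect_error(set_parameters(base_params, no_such = 1), "unknown")
})
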