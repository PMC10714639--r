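published_results <- tibble::tibble(
  strategy = c("prp-only", "prp-first", "antivegf-first", "antivegf-only"),
  cost_healthcare = c(9153, 10894, 12834, 15446),
  cost_payer = c(5132, 4477, 4053, 3361),
  cost_societal = c(85188, 81536, 76737, 70366),
  qaly = c(13.07, 13.09, 13.18, 13.26))

test_that("incremental analysis reproduces the published worked example", {
  inc <- incremental_vs_comparator(published_results, "prp-only",
                                   "healthcare")
  av <- inc[inc$strategy == "antivegf-only", ]
  expect_equal(av$delta_cost, 6293)
  expect_equal(av$delta_qaly, 0.19, tolerance = 1e-12)
  expect_equal(av$icer, 33121.05263, tolerance = 1e-7)
  expect_equal(av$label, "")

  pay <- incremental_vs_comparator(published_results, "prp-only", "payer")
  af <- pay[pay$strategy == "antivegf-first", ]
  expect_equal(af$delta_cost, -1079)
  expect_equal(af$delta_qaly, 0.11, tolerance = 1e-12)
  expect_true(is.na(af$icer))
  expect_equal(af$label, "cost-saving")
  expect_true(all(pay$label[pay$strategy != "prp-only"] == "cost-saving"))

  # comparator row carries empty increments
  cmp <- inc[inc$strategy == "prp-only", ]
  expect_true(is.na(cmp$delta_cost) && is.na(cmp$icer))
})

test_that("degenerate increments are labelled, never divided", {
  two <- tibble::tibble(strategy = c("a", "b"),
                        cost_healthcare = c(100, 100), qaly = c(1, 1))
  inc <- incremental_vs_comparator(two, "a")
  expect_equal(inc$delta_cost[2], 0)
  expect_true(is.na(inc$icer[2]))
  expect_equal(inc$label[2], "")

  two$cost_healthcare <- c(100, 150)  # costlier, no QALY gain
  expect_equal(incremental_vs_comparator(two, "a")$label[2], "dominated")
  two$cost_healthcare <- c(100, 50)
  expect_equal(incremental_vs_comparator(two, "a")$label[2], "cost-saving")
  expect_error(incremental_vs_comparator(two, "missing"), "comparator")
})

test_that("net monetary benefit is linear and anchored at -cost", {
  one <- published_results[published_results$strategy == "prp-only", ]
  expect_equal(nmb(one, 0)$nmb, -9153)
  expect_equal(nmb(one, 24400)$nmb, 309755)
  grid <- nmb(one, c(0, 10000, 20000, 50000))
  expect_true(all(diff(grid$nmb) > 0))
  expect_error(nmb(one, -5), "non-negative")
})

test_that("efficiency frontier classifies strict and extended dominance", {
  two <- tibble::tibble(strategy = c("cheap_good", "costly_bad"),
                        cost_healthcare = c(100, 200), qaly = c(2, 1))
  fr <- efficiency_frontier(two)
  expect_equal(fr$status[fr$strategy == "costly_bad"], "dominated")
  expect_equal(fr$status[fr$strategy == "cheap_good"], "frontier")

  # three collinear strategies: the middle one stays on the frontier
  col3 <- tibble::tibble(strategy = c("a", "b", "c"),
                         cost_healthcare = c(100, 200, 300),
                         qaly = c(1, 2, 3))
  expect_true(all(efficiency_frontier(col3)$status == "frontier"))

  # a classic extended-dominance middle point
  ext <- tibble::tibble(strategy = c("a", "b", "c"),
                        cost_healthcare = c(0, 1000, 1100),
                        qaly = c(0, 0.1, 1))
  fr <- efficiency_frontier(ext)
  expect_equal(fr$status[fr$strategy == "b"], "ext-dominated")
  expect_equal(fr$status[fr$strategy %in% c("a", "c")],
               rep("frontier", 2))
})

test_that("frontier equals the brute-force NMB oracle on random instances", {
  set.seed(2024)
  for (trial in 1:200) {
    inst <- random_frontier_instance(sample(2:6, 1))
    fr <- efficiency_frontier(inst)
    expect_setequal(fr$strategy[fr$status == "frontier"],
                    frontier_oracle(tibble::tibble(
                      strategy = inst$strategy,
                      cost = inst$cost_healthcare, qaly = inst$qaly)))
    # invariance to input ordering
    fr2 <- efficiency_frontier(inst[sample(nrow(inst)), ])
    expect_equal(dplyr::arrange(fr, strategy),
                 dplyr::arrange(fr2, strategy))
  }
})

test_that("the maximal-NMB strategy always sits on the frontier", {
  set.seed(55)
  for (trial in 1:50) {
    inst <- random_frontier_instance(5)
    fr <- efficiency_frontier(inst)
    w <- stats::runif(1, 0, 80000)
    b <- nmb(inst, w)
    best <- b$strategy[which.max(b$nmb)]
    expect_true(best %in% fr$strategy[fr$status == "frontier"])
  }
})

test_that("display formatting mirrors the published table layout", {
  inc <- incremental_vs_comparator(published_results, "prp-only", "payer")
  fmt <- format_incremental(inc)
  expect_equal(fmt$incremental_cost[fmt$strategy == "prp-only"], "")
  expect_equal(fmt$icer[fmt$strategy == "antivegf-only"], "Cost-saving")
  expect_equal(fmt$cost[fmt$strategy == "prp-only"], "5,132")
})
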