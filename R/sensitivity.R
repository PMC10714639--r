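# One-way deterministic sensitivity analysis (tornado) and probabilistic
# sensitivity analysis with cost-effectiveness acceptability curves.

# pairwise ICER (strategy vs comparator) under a given parameter set
pairwise_icer <- function(params, strategy, comparator, perspective, lt,
                          settings = cohort_settings()) {
  plist <- if (inherits(params, "pdr_params")) param_values(params) else params
  col <- perspective_col(perspective)
  res <- run_all_strategies(plist, lt, settings,
                            strategies = c(comparator, strategy))
  dc <- res[[col]][2] - res[[col]][1]
  dq <- res$qaly[2] - res$qaly[1]
  dc / dq
}

#' One-way sensitivity of a pairwise ICER to a single parameter
#'
#' Recomputes the ICER of `strategy` vs `comparator` with the named
#' parameter set to its low and then its high sensitivity bound, all other
#' parameters at base. Bounds are the published 95% CI for relative risks
#' and ±20% of base otherwise.
#'
#' @param param Canonical parameter name.
#' @param strategy,comparator Strategy names for the pairwise ICER (the
#'   published tornado contrasts anti-VEGF-only with PRP-only).
#' @param perspective Cost perspective.
#' @param params A `pdr_params` tibble.
#' @param lt A `pdr_life_table`.
#' @param settings A [cohort_settings()] list.
#' @param .base_icer Precomputed base-case ICER (used by [tornado()] to
#'   avoid recomputing it per parameter); left `NULL` to compute.
#' @return A one-row tibble: `parameter`, `low`, `high`, `icer_base`,
#'   `icer_low`, `icer_high`, `swing = |icer_high - icer_low|`.
#' @export
one_way <- function(param, strategy = "antivegf-only",
                    comparator = "prp-only", perspective = "healthcare",
                    params = default_parameters(),
                    lt = gompertz_life_table(),
                    settings = cohort_settings(), .base_icer = NULL) {
  if (!param %in% params$name)
    stop("unknown parameter: ", param, call. = FALSE)
  row <- params[params$name == param, ]
  base_icer <- .base_icer %||%
    pairwise_icer(params, strategy, comparator, perspective, lt, settings)
  icer_low <- pairwise_icer(at_bound(params, param, "low"), strategy,
                            comparator, perspective, lt, settings)
  icer_high <- pairwise_icer(at_bound(params, param, "high"), strategy,
                             comparator, perspective, lt, settings)
  tibble::tibble(parameter = param, low = row$low, high = row$high,
                 icer_base = base_icer, icer_low = icer_low,
                 icer_high = icer_high,
                 swing = abs(icer_high - icer_low))
}

#' Tornado analysis of a pairwise comparison
#'
#' Runs [one_way()] for every parameter with a sensitivity range and sorts
#' the entries by descending ICER swing.
#'
#' @inheritParams one_way
#' @return A tibble of class `pdr_tornado`, one row per ranged parameter,
#'   sorted by descending `swing`.
#' @export
tornado <- function(strategy = "antivegf-only", comparator = "prp-only",
                    perspective = "healthcare",
                    params = default_parameters(),
                    lt = gompertz_life_table(),
                    settings = cohort_settings()) {
  ranged <- params$name[params$low < params$high]
  base_icer <- pairwise_icer(params, strategy, comparator, perspective, lt,
                             settings)
  rows <- purrr::map_dfr(ranged, one_way, strategy = strategy,
                         comparator = comparator, perspective = perspective,
                         params = params, lt = lt, settings = settings,
                         .base_icer = base_icer)
  rows <- dplyr::arrange(rows, dplyr::desc(.data$swing))
  structure(rows, class = c("pdr_tornado", "tbl_df", "tbl", "data.frame"),
            strategy = strategy, comparator = comparator,
            perspective = perspective)
}

#' Tornado diagram
#'
#' @param object A `pdr_tornado` tibble.
#' @param top Show only the `top` largest swings (default 15).
#' @param ... Unused.
#' @return A ggplot object: horizontal ICER bars from the low- and
#'   high-bound runs around the base-case ICER.
#' @export
autoplot.pdr_tornado <- function(object, top = 15, ...) {
  tbl <- utils::head(dplyr::arrange(tibble::as_tibble(object),
                                    dplyr::desc(.data$swing)), top)
  tbl$parameter <- factor(tbl$parameter, levels = rev(tbl$parameter))
  long <- tidyr::pivot_longer(tbl, c("icer_low", "icer_high"),
                              names_to = "bound", values_to = "icer")
  ggplot2::ggplot(long) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_base,
                                       xend = .data$icer,
                                       y = .data$parameter,
                                       yend = .data$parameter,
                                       colour = .data$bound),
                          linewidth = 3) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$icer_base),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(icer_low = "#4477AA", icer_high = "#CC6677"),
      labels = c(icer_low = "low bound", icer_high = "high bound")) +
    ggplot2::labs(x = "ICER (USD/QALY)", y = NULL, colour = NULL,
                  title = paste0("One-way sensitivity: ",
                                 attr(object, "strategy"), " vs ",
                                 attr(object, "comparator"))) +
    ggplot2::theme_minimal()
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` joint parameter sets from the PSA distributions (see
#' [sample_parameter_set()]) and runs the full cohort model for every
#' strategy under each draw, recording discounted lifetime cost per
#' perspective and QALYs. Reproducible under `seed`.
#'
#' @param n Number of parameter draws.
#' @param seed Integer seed.
#' @param params A `pdr_params` tibble (base values define the
#'   distributions).
#' @param lt A `pdr_life_table`.
#' @param settings A [cohort_settings()] list.
#' @param strategies Strategy names (default: all four).
#' @return An object of class `pdr_psa`: a list with `draws` (a tibble:
#'   `draw`, `strategy`, `cost_payer`, `cost_healthcare`, `cost_societal`,
#'   `qaly`), `n`, and `seed`.
#' @export
psa_run <- function(n, seed = 1, params = default_parameters(),
                    lt = gompertz_life_table(),
                    settings = cohort_settings(),
                    strategies = pdr_strategies()) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  out <- vector("list", n)
  for (d in seq_len(n)) {
    drawn <- sample_parameter_set(params, seed = NULL)
    res <- run_all_strategies(drawn, lt, settings, strategies = strategies)
    res$draw <- d
    out[[d]] <- res
  }
  draws <- dplyr::relocate(dplyr::bind_rows(out), "draw")
  structure(list(draws = draws, n = n, seed = seed,
                 strategies = strategies),
            class = "pdr_psa")
}

#' @export
print.pdr_psa <- function(x, ...) {
  cat("Probabilistic sensitivity analysis:", x$n, "draws, seed", x$seed, "\n")
  print(glance(x))
  invisible(x)
}

#' Per-draw PSA results
#'
#' @param x A `pdr_psa` object.
#' @param ... Unused.
#' @return The per-draw results tibble.
#' @export
tidy.pdr_psa <- function(x, ...) x$draws

#' Summarise a PSA by strategy
#'
#' @param x A `pdr_psa` object.
#' @param ... Unused.
#' @return A tibble per strategy: mean and SE of discounted cost (each
#'   perspective) and QALYs over the draws.
#' @export
glance.pdr_psa <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$draws, .data$strategy),
    dplyr::across(c("cost_payer", "cost_healthcare", "cost_societal", "qaly"),
                  list(mean = mean,
                       se = ~ stats::sd(.x) / sqrt(dplyr::n()))),
    .groups = "drop")
}

#' Cost-effectiveness acceptability curves
#'
#' For every willingness-to-pay value on the grid, the fraction of PSA
#' draws in which each strategy attains the maximal net monetary benefit;
#' ties are split equally, so probabilities sum to 1 at every grid point.
#'
#' @param psa A `pdr_psa` object (or its `draws` tibble).
#' @param wtp_grid WTP grid, USD/QALY (default 0-100,000 in 1,000 steps).
#' @param perspective Cost perspective.
#' @return A tibble of class `pdr_ceac`: `wtp`, `strategy`, `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 1000),
                 perspective = "healthcare") {
  draws <- if (inherits(psa, "pdr_psa")) psa$draws else psa
  if (nrow(draws) == 0) stop("empty PSA output", call. = FALSE)
  col <- perspective_col(perspective)
  strategies <- sort(unique(draws$strategy))
  ns <- length(strategies)
  # draws x strategy matrices
  wide_c <- tidyr::pivot_wider(draws[, c("draw", "strategy", col)],
                               names_from = "strategy",
                               values_from = dplyr::all_of(col))
  wide_q <- tidyr::pivot_wider(draws[, c("draw", "strategy", "qaly")],
                               names_from = "strategy",
                               values_from = "qaly")
  C <- as.matrix(wide_c[, strategies])
  Q <- as.matrix(wide_q[, strategies])
  out <- purrr::map_dfr(wtp_grid, function(w) {
    B <- w * Q - C
    best <- B == matrixStats_rowMaxs(B)
    share <- best / rowSums(best)
    tibble::tibble(wtp = w, strategy = strategies,
                   probability = unname(colMeans(share)))
  })
  structure(out, class = c("pdr_ceac", "tbl_df", "tbl", "data.frame"),
            perspective = perspective)
}

# row maxima without an extra dependency
matrixStats_rowMaxs <- function(m) {
  do.call(pmax, as.data.frame(m))
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param object A `pdr_ceac` tibble.
#' @param ... Unused.
#' @return A ggplot object: probability each strategy is optimal vs WTP.
#' @export
autoplot.pdr_ceac <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$wtp, .data$probability,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "Probability cost-effective", colour = "Strategy",
                  title = paste0("CEAC (", attr(object, "perspective"),
                                 " perspective)")) +
    ggplot2::theme_minimal()
}

#' WTP at which one strategy overtakes another on the CEAC
#'
#' Finds the smallest willingness-to-pay at which strategy `b`'s
#' probability of being optimal first exceeds strategy `a`'s, linearly
#' interpolating the crossing between grid points.
#'
#' @param curve A `pdr_ceac` tibble.
#' @param a,b Strategy names (looking for the `a` to `b` hand-over).
#' @return The interpolated WTP in USD/QALY, or `NA` if the curves never
#'   cross on the grid.
#' @export
threshold_wtp <- function(curve, a, b) {
  tbl <- tibble::as_tibble(curve)
  if (!all(c(a, b) %in% tbl$strategy))
    stop("both strategies must be present in the CEAC", call. = FALSE)
  pa <- tbl[tbl$strategy == a, ]
  pb <- tbl[tbl$strategy == b, ]
  pa <- dplyr::arrange(pa, .data$wtp)
  pb <- dplyr::arrange(pb, .data$wtp)
  d <- pb$probability - pa$probability
  over <- which(d > 0)
  if (length(over) == 0) return(NA_real_)
  k <- over[1]
  if (k == 1) return(pa$wtp[1])
  # linear interpolation of the sign change in d between grid points
  w0 <- pa$wtp[k - 1]; w1 <- pa$wtp[k]
  d0 <- d[k - 1]; d1 <- d[k]
  if (d1 == d0) return(w1)
  w0 + (0 - d0) / (d1 - d0) * (w1 - w0)
}
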