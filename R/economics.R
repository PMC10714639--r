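# Incremental cost-effectiveness analysis, dominance, net monetary benefit.

perspective_col <- function(perspective) {
  perspective <- match.arg(perspective, c("payer", "healthcare", "societal"))
  paste0("cost_", perspective)
}

#' Incremental analysis against a fixed comparator
#'
#' Computes the incremental cost, incremental effectiveness, and ICER of
#' every strategy against a common comparator (the published comparisons
#' use PRP-only). The ICER is reported only when both increments are
#' positive; a strategy that saves cost without losing effectiveness is
#' labelled `cost-saving`, and one that adds cost without gaining
#' effectiveness is labelled `dominated`.
#'
#' @param results A tibble from [run_all_strategies()] (columns `strategy`,
#'   `cost_*`, `qaly`).
#' @param comparator Comparator strategy name (default `"prp-only"`).
#' @param perspective `"payer"`, `"healthcare"`, or `"societal"`.
#' @return A tibble with one row per strategy: `strategy`, `comparator`,
#'   `cost`, `qaly`, `delta_cost`, `delta_qaly`, `icer` (NA when a label
#'   applies), `label` (`""`, `"cost-saving"`, or `"dominated"`; the
#'   comparator row has empty increments).
#' @examples
#' res <- tibble::tibble(strategy = c("prp-only", "antivegf-only"),
#'                       cost_healthcare = c(9153, 15446),
#'                       qaly = c(13.07, 13.26))
#' incremental_vs_comparator(res, perspective = "healthcare")
#' @export
incremental_vs_comparator <- function(results, comparator = "prp-only",
                                      perspective = "healthcare") {
  col <- perspective_col(perspective)
  if (!comparator %in% results$strategy)
    stop("comparator ", comparator, " not present in results", call. = FALSE)
  base <- results[results$strategy == comparator, ]
  dplyr::mutate(
    tibble::tibble(strategy = results$strategy, comparator = comparator,
                   cost = results[[col]], qaly = results$qaly),
    delta_cost = ifelse(.data$strategy == comparator, NA_real_,
                        .data$cost - base[[col]]),
    delta_qaly = ifelse(.data$strategy == comparator, NA_real_,
                        .data$qaly - base$qaly),
    icer = dplyr::case_when(
      .data$strategy == comparator ~ NA_real_,
      .data$delta_cost > 0 & .data$delta_qaly > 0 ~
        .data$delta_cost / .data$delta_qaly,
      TRUE ~ NA_real_),
    label = dplyr::case_when(
      .data$strategy == comparator ~ "",
      .data$delta_cost < 0 & .data$delta_qaly >= 0 ~ "cost-saving",
      .data$delta_cost >= 0 & .data$delta_qaly <= 0 &
        !(.data$delta_cost == 0 & .data$delta_qaly == 0) ~ "dominated",
      .data$delta_cost <= 0 & .data$delta_qaly < 0 ~ "icer-sw-quadrant",
      .data$delta_cost == 0 & .data$delta_qaly == 0 ~ "",
      TRUE ~ ""))
}

#' Cost-effectiveness efficiency frontier
#'
#' Orders strategies by cost, removes strictly dominated strategies
#' (costlier and no more effective than another) and extendedly dominated
#' ones (off the convex hull: their incremental ICER exceeds that of the
#' next frontier step), and reports sequential frontier ICERs.
#'
#' @inheritParams incremental_vs_comparator
#' @return A tibble of all strategies sorted by cost with columns
#'   `strategy`, `cost`, `qaly`, `status` (`"frontier"`,
#'   `"dominated"`, `"ext-dominated"`), and `icer` (sequential ICER along
#'   the frontier; NA for the cheapest frontier strategy and for dominated
#'   ones).
#' @export
efficiency_frontier <- function(results, perspective = "healthcare") {
  col <- perspective_col(perspective)
  if (nrow(results) < 2)
    stop("frontier needs at least two strategies", call. = FALSE)
  tbl <- tibble::tibble(strategy = results$strategy,
                        cost = results[[col]], qaly = results$qaly)
  tbl <- dplyr::arrange(tbl, .data$cost, .data$qaly)
  n <- nrow(tbl)
  status <- rep("frontier", n)
  # strict dominance: another strategy costs no more and yields at least
  # as much effect, with at least one strict inequality
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (tbl$cost[j] <= tbl$cost[i] && tbl$qaly[j] >= tbl$qaly[i] &&
          (tbl$cost[j] < tbl$cost[i] || tbl$qaly[j] > tbl$qaly[i])) {
        status[i] <- "dominated"
        break
      }
    }
  }
  # extended dominance: repeatedly drop frontier candidates whose
  # incremental ICER exceeds that of the next step up
  repeat {
    idx <- which(status == "frontier")
    if (length(idx) < 3) break
    sub <- tbl[idx, ]
    icers <- diff(sub$cost) / diff(sub$qaly)
    bad <- which(diff(icers) < 0)
    if (length(bad) == 0) break
    status[idx[bad[1] + 1]] <- "ext-dominated"
  }
  idx <- which(status == "frontier")
  icer <- rep(NA_real_, n)
  if (length(idx) > 1)
    icer[idx[-1]] <- diff(tbl$cost[idx]) / diff(tbl$qaly[idx])
  dplyr::mutate(tbl, status = status, icer = icer)
}

#' Net monetary benefit
#'
#' `NMB = WTP x QALY - cost` at a willingness-to-pay threshold; the
#' strategy with maximal NMB is optimal at that threshold.
#'
#' @param results A results tibble (or one row) with `cost_*` and `qaly`.
#' @param wtp Willingness to pay, USD per QALY (non-negative; vectorised).
#' @param perspective `"payer"`, `"healthcare"`, or `"societal"`.
#' @return A tibble with columns `strategy`, `wtp`, `nmb` (USD).
#' @examples
#' res <- tibble::tibble(strategy = "prp-only",
#'                       cost_healthcare = 9153, qaly = 13.07)
#' nmb(res, 24400)  # 309755
#' @export
nmb <- function(results, wtp, perspective = "healthcare") {
  if (any(wtp < 0)) stop("wtp must be non-negative", call. = FALSE)
  col <- perspective_col(perspective)
  tidyr::crossing(tibble::tibble(strategy = results$strategy,
                                 cost = results[[col]],
                                 qaly = results$qaly),
                  wtp = wtp) |>
    dplyr::mutate(nmb = .data$wtp * .data$qaly - .data$cost) |>
    dplyr::select("strategy", "wtp", "nmb")
}

#' Format an incremental table for display
#'
#' Rounds monetary columns to whole dollars and replaces labelled cells the
#' way published base-case tables print them (empty comparator cells,
#' dominance labels in the ICER column).
#'
#' @param inc Output of [incremental_vs_comparator()].
#' @return A character-formatted tibble suitable for printing/CSV export.
#' @export
format_incremental <- function(inc) {
  fmt_money <- function(x) ifelse(is.na(x), "",
                                  formatC(round(x), format = "d", big.mark = ","))
  tibble::tibble(
    strategy = inc$strategy,
    cost = fmt_money(inc$cost),
    incremental_cost = fmt_money(inc$delta_cost),
    qaly = ifelse(is.na(inc$qaly), "", sprintf("%.2f", inc$qaly)),
    incremental_qaly = ifelse(is.na(inc$delta_qaly), "",
                              sprintf("%.2f", inc$delta_qaly)),
    icer = dplyr::case_when(
      !is.na(inc$icer) ~ fmt_money(inc$icer),
      inc$label == "cost-saving" ~ "Cost-saving",
      inc$label == "dominated" ~ "Dominated",
      TRUE ~ ""))
}
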