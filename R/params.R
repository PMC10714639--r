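# Model parameters: registry, validation, file loading, PSA samplers.

# Registry of every parameter the model consumes. `base` is the point
# estimate; `low`/`high` are the one-way sensitivity bounds (±20% of base
# unless a published 95% CI is available, in which case the CI is used);
# `dist` is the PSA family. Utilities are stored as the value at age 50
# (the upper end of the printed range); the age-100 value is base minus
# `utility_age_span`. Monetary values are 2020 USD.
registry_cache <- new.env(parent = emptyenv())

param_registry <- function() {
  if (!is.null(registry_cache$tbl)) return(registry_cache$tbl)
  p <- function(name, base, dist, units, low = 0.8 * base, high = 1.2 * base,
                ci_lo = NA_real_, ci_hi = NA_real_, rule = "custom") {
    tibble::tibble(name = name, base = base, low = low, high = high,
                   dist = dist, ci_lo = ci_lo, ci_hi = ci_hi, units = units,
                   range_rule = rule)
  }
  prob <- function(name, base, dist = "beta")
    p(name, base, dist, "probability", high = min(1, 1.2 * base),
      rule = "pct20")
  cost <- function(name, base) p(name, base, "gamma", "USD", rule = "pct20")
  util <- function(name, base)
    p(name, base, "triangle", "utility", rule = "pct20")
  rr <- function(name, base, ci_lo, ci_hi)
    p(name, base, "lognormal", "relative_risk",
      low = ci_lo, high = ci_hi, ci_lo = ci_lo, ci_hi = ci_hi, rule = "ci")

  registry_cache$tbl <- dplyr::bind_rows(
    # transition probabilities
    prob("p_NPDR_to_DME", 0.1522),
    prob("p_PDR_to_DME", 0.179),
    prob("p_PDR_to_SVL", 0.18, dist = "triangle"),
    prob("p_PRP_success", 0.2008),
    prob("p_recur_post_PRP", 0.0169),
    prob("p_antiVEGF_DME_success", 0.534),
    prob("p_endoph_per_injection", 0.0006),
    prob("p_endoph_treat_success", 0.595),
    prob("p_loss_followup", 0.2, dist = "triangle"),
    # anti-VEGF continuation in SVL by tenure year (fixed in PSA)
    prob("svl_continuation_y1", 0.914, dist = "fixed"),
    prob("svl_continuation_y2", 0.736, dist = "fixed"),
    prob("svl_continuation_y3", 0.650, dist = "fixed"),
    prob("svl_continuation_y4", 0.609, dist = "fixed"),
    prob("svl_continuation_y5", 0.537, dist = "fixed"),
    prob("svl_continuation_y5plus", 0.481, dist = "fixed"),
    # relative risks (95% CIs where published)
    rr("rr_antiVEGF_vs_PRP_effect", 1.75, 1.12, 2.75),
    rr("rr_recur_antiVEGF_vs_PRP", 1.15, 0.63, 2.12),
    rr("rr_death_diabetes", 1.49, 1.45, 1.54),
    # no CI published for the SVL mortality RR: ±20% band stands in
    p("rr_death_SVL", 11.54, "lognormal", "relative_risk", rule = "pct20"),
    # annual state costs, by component
    cost("cost_NPDR_covered", 160), cost("cost_NPDR_noncovered", 12),
    cost("cost_NPDR_transport", 4), cost("cost_NPDR_time", 82),
    cost("cost_PDR_covered", 348), cost("cost_PDR_noncovered", 44),
    cost("cost_PDR_transport", 10), cost("cost_PDR_time", 147),
    cost("cost_DME_covered", 1732), cost("cost_DME_noncovered", 267),
    cost("cost_DME_transport", 24), cost("cost_DME_time", 375),
    cost("cost_SVL_covered", 338), cost("cost_SVL_noncovered", 49),
    cost("cost_SVL_transport", 12), cost("cost_SVL_time", 162),
    cost("cost_SVL_care", 11826), cost("cost_SVL_glasses", 27),
    # per-episode treatment costs, by component
    cost("cost_PRP_covered", 188), cost("cost_PRP_noncovered", 24),
    cost("cost_PRP_transport", 2), cost("cost_PRP_time", 32),
    cost("cost_antiVEGF_covered", 447), cost("cost_antiVEGF_noncovered", 63),
    cost("cost_antiVEGF_transport", 2), cost("cost_antiVEGF_time", 25),
    cost("cost_endoph_covered", 2143), cost("cost_endoph_noncovered", 1208),
    cost("cost_endoph_transport", 2), cost("cost_endoph_time", 232),
    # utilities at age 50 (upper end of printed range); span to age 100 fixed
    util("u_NPDR", 0.904), util("u_PDR", 0.901),
    util("u_DME", 0.912), util("u_SVL", 0.851),
    p("utility_age_span", 0.055, "fixed", "utility",
      low = 0.055, high = 0.055),
    p("disutility_pVFD", 0.01, "fixed", "utility", low = 0.005, high = 0.02),
    # discounting and decision threshold
    p("discount_rate", 0.045, "fixed", "rate", low = 0.03, high = 0.07),
    p("wtp_threshold", 24400, "fixed", "USD",
      low = 24400, high = 24400)
  )
  registry_cache$tbl
}

#' Base-case model parameters
#'
#' Returns the full base-case parameter set: transition probabilities,
#' treatment success rates, mortality relative risks, per-state annual costs
#' and per-episode treatment costs split by component (covered / non-covered
#' medical, transportation, time, care), health-state utilities, and the
#' annual discount rate. Each row carries its one-way sensitivity bounds
#' (`low`, `high`) and the distribution family used in probabilistic
#' sensitivity analysis (`dist`), with 95% CIs for the lognormal relative
#' risks.
#'
#' Utilities are stored as the value at age 50; the model interpolates
#' linearly down by `utility_age_span` over ages 50-100.
#'
#' @return A tibble of class `pdr_params` with columns `name`, `value`,
#'   `base`, `low`, `high`, `dist`, `ci_lo`, `ci_hi`, `units`, and a
#'   `provenance` attribute (`"base"`, `"dsa-low"`, `"dsa-high"`, or
#'   `"psa-draw"`).
#' @examples
#' params <- default_parameters()
#' dplyr::filter(params, name == "p_PRP_success")$value
#' @export
default_parameters <- function() {
  reg <- param_registry()
  out <- dplyr::mutate(reg, value = .data$base, .before = "base")
  new_pdr_params(out, provenance = "base")
}

new_pdr_params <- function(tbl, provenance = "base", seed = NA_integer_) {
  structure(tbl, class = c("pdr_params", "tbl_df", "tbl", "data.frame"),
            provenance = provenance, seed = seed)
}

#' Extract parameter values as a named list
#'
#' @param params A `pdr_params` tibble.
#' @return Named list of numeric values keyed by canonical parameter name.
#' @export
param_values <- function(params) {
  stats::setNames(as.list(params$value), params$name)
}

pv <- function(plist, name) {
  v <- plist[[name]]
  if (is.null(v)) stop("unknown parameter: ", name, call. = FALSE)
  v
}

#' Set parameter values by name
#'
#' @param params A `pdr_params` tibble.
#' @param ... Named numeric overrides, e.g. `p_PRP_success = 0.3`.
#' @param provenance Provenance tag recorded on the result.
#' @return The modified `pdr_params` tibble, revalidated.
#' @export
set_parameters <- function(params, ..., provenance = "base") {
  overrides <- list(...)
  if (length(overrides) == 0) return(params)
  bad <- setdiff(names(overrides), params$name)
  if (length(bad) > 0)
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (nm in names(overrides)) {
    params$value[params$name == nm] <- overrides[[nm]]
  }
  validate_parameters(params)
  new_pdr_params(params, provenance = provenance)
}

#' Validate a parameter set
#'
#' Checks the type invariants: probabilities in \[0, 1\], costs non-negative,
#' relative risks positive, utilities in \[0, 1\], and `low <= base <= high`
#' for every ranged parameter.
#'
#' @param params A `pdr_params` tibble.
#' @return Invisibly, `params`; errors name the offending parameter.
#' @export
validate_parameters <- function(params) {
  required <- param_registry()$name
  missing <- setdiff(required, params$name)
  if (length(missing) > 0)
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  check <- function(cond, nm, what) {
    if (!all(cond))
      stop("parameter ", nm[!cond][1], " violates invariant: ", what,
           call. = FALSE)
  }
  with_units <- function(u) params[params$units %in% u, , drop = FALSE]
  pr <- with_units("probability")
  check(pr$value >= 0 & pr$value <= 1, pr$name, "probability must lie in [0, 1]")
  co <- with_units("USD")
  check(co$value >= 0, co$name, "cost must be non-negative")
  rr <- with_units("relative_risk")
  check(rr$value > 0, rr$name, "relative risk must be positive")
  ut <- with_units("utility")
  check(ut$value >= 0 & ut$value <= 1, ut$name, "utility must lie in [0, 1]")
  ranged <- params[params$low < params$high, , drop = FALSE]
  check(ranged$low <= ranged$base & ranged$base <= ranged$high,
        ranged$name, "low <= base <= high")
  invisible(params)
}

#' Load parameters from a YAML file
#'
#' The file is a flat `name: value` mapping using the canonical parameter
#' names of [default_parameters()]; an optional `distributions` block may
#' override the PSA family and 95% CI of individual parameters, e.g.
#' `distributions: {rr_death_SVL: {dist: lognormal, ci: [9.0, 14.5]}}`.
#' Unknown keys are rejected. When `fill_defaults` is `TRUE`, keys not
#' present in the file keep their base-case values; otherwise the file must
#' specify every parameter.
#'
#' @param path Path to the YAML parameter file.
#' @param fill_defaults Fill unspecified parameters from the base case?
#' @return A validated `pdr_params` tibble.
#' @export
load_parameters <- function(path, fill_defaults = TRUE) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  dists <- raw[["distributions"]]
  raw[["distributions"]] <- NULL
  params <- default_parameters()
  unknown <- setdiff(names(raw), params$name)
  if (length(unknown) > 0)
    stop("unknown parameter key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!fill_defaults) {
    missing <- setdiff(params$name, names(raw))
    if (length(missing) > 0)
      stop("parameter file missing key(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  for (nm in names(raw)) {
    v <- raw[[nm]]
    if (!is.numeric(v) || length(v) != 1)
      stop("parameter ", nm, " must be a single number", call. = FALSE)
    i <- which(params$name == nm)
    params$value[i] <- v
    params$base[i] <- v
    # re-derive the sensitivity bounds around the new base
    if (params$range_rule[i] == "pct20") {
      params$low[i] <- 0.8 * v
      params$high[i] <- if (params$units[i] == "probability")
        min(1, 1.2 * v) else 1.2 * v
    } else {
      params$low[i] <- min(params$low[i], v)
      params$high[i] <- max(params$high[i], v)
    }
  }
  if (!is.null(dists)) {
    unknown <- setdiff(names(dists), params$name)
    if (length(unknown) > 0)
      stop("distributions block names unknown parameter(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    for (nm in names(dists)) {
      d <- dists[[nm]]
      if (!is.null(d$dist)) params$dist[params$name == nm] <- d$dist
      if (!is.null(d$ci)) {
        i <- which(params$name == nm)
        params$ci_lo[i] <- d$ci[[1]]
        params$ci_hi[i] <- d$ci[[2]]
        # a supplied CI becomes the sensitivity range (the RR convention)
        params$range_rule[i] <- "ci"
        params$low[i] <- min(d$ci[[1]], params$base[i])
        params$high[i] <- max(d$ci[[2]], params$base[i])
      }
    }
  }
  validate_parameters(params)
  new_pdr_params(params)
}

# Inverse-CDF sampler for the triangular distribution.
rtriangle <- function(n, min, mode, max) {
  if (max <= min) return(rep(min, n))
  u <- stats::runif(n)
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

#' Construct the PSA sampling distribution for one parameter
#'
#' Beta and gamma families are fit by the method of moments with mean equal
#' to the base value and standard error `0.2 * base / 1.96` (the ±20%
#' sensitivity band read as a 95% interval). Lognormal uses
#' `mu = log(base)` and `sigma = (log(ci_hi) - log(ci_lo)) / (2 * 1.96)`;
#' when no CI is recorded, the ±20% band stands in. Triangle uses
#' `(low, base, high)`. Fixed parameters always return the base value.
#'
#' @param param A one-row slice of a `pdr_params` tibble (or a list with
#'   fields `name`, `base`, `low`, `high`, `dist`, `ci_lo`, `ci_hi`).
#' @return A list with elements `family`, the fitted shape values, and a
#'   `draw(n)` function.
#' @examples
#' p <- dplyr::filter(default_parameters(), name == "rr_antiVEGF_vs_PRP_effect")
#' build_sampler(p)$meanlog  # log(1.75)
#' @export
build_sampler <- function(param) {
  base <- param$base
  se <- 0.2 * base / 1.96
  switch(param$dist,
    fixed = list(family = "fixed", value = base,
                 draw = function(n) rep(base, n)),
    beta = {
      if (base <= 0 || base >= 1)
        stop("beta requires base in (0, 1): ", param$name, call. = FALSE)
      nu <- base * (1 - base) / se^2 - 1
      shape1 <- base * nu
      shape2 <- (1 - base) * nu
      list(family = "beta", shape1 = shape1, shape2 = shape2,
           draw = function(n) stats::rbeta(n, shape1, shape2))
    },
    gamma = {
      if (base < 0) stop("gamma requires base >= 0: ", param$name, call. = FALSE)
      if (base == 0) {
        list(family = "fixed", value = 0, draw = function(n) rep(0, n))
      } else {
        shape <- (base / se)^2
        rate <- base / se^2
        list(family = "gamma", shape = shape, rate = rate,
             draw = function(n) stats::rgamma(n, shape, rate))
      }
    },
    lognormal = {
      if (base <= 0)
        stop("lognormal requires positive base: ", param$name, call. = FALSE)
      ci_lo <- param$ci_lo
      ci_hi <- param$ci_hi
      if (is.na(ci_lo) || is.na(ci_hi)) {
        ci_lo <- 0.8 * base
        ci_hi <- 1.2 * base
      }
      meanlog <- log(base)
      sdlog <- (log(ci_hi) - log(ci_lo)) / (2 * 1.96)
      list(family = "lognormal", meanlog = meanlog, sdlog = sdlog,
           draw = function(n) stats::rlnorm(n, meanlog, sdlog))
    },
    triangle = list(family = "triangle",
                    min = param$low, mode = base, max = param$high,
                    draw = function(n) rtriangle(n, param$low, base, param$high)),
    stop("unknown distribution family: ", param$dist, call. = FALSE)
  )
}

# One value from a parameter's PSA distribution, respecting the domain of
# its unit type. Out-of-domain draws are rejected and redrawn (keeps the
# stated family); utilities are the exception, censored to 1 as specified.
draw_one <- function(sampler, units) {
  x <- sampler$draw(1)
  if (units == "utility") return(min(x, 1))
  ok <- switch(units,
               probability = function(v) v >= 0 && v <= 1,
               USD = function(v) v >= 0,
               relative_risk = function(v) v > 0,
               rate = function(v) v >= 0,
               function(v) TRUE)
  tries <- 0
  while (!ok(x)) {
    tries <- tries + 1
    if (tries > 1000)
      stop("rejection sampling failed to find an in-domain draw", call. = FALSE)
    x <- sampler$draw(1)
  }
  x
}

#' Draw one joint parameter set for probabilistic sensitivity analysis
#'
#' Every parameter with a non-fixed PSA family is replaced by an independent
#' draw from its distribution (see [build_sampler()]). Draws outside the
#' parameter's domain are rejected and redrawn so the stated family is
#' preserved; sampled utilities above 1 are censored to 1. Fixed parameters
#' keep their base value. Reproducible given `seed`.
#'
#' @param base A `pdr_params` tibble (base values define the distributions).
#' @param seed Integer seed; when `NULL` the current RNG stream is used
#'   (as in a PSA loop).
#' @return A `pdr_params` tibble with provenance `"psa-draw"`.
#' @export
sample_parameter_set <- function(base, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vals <- base$value
  # plain-vector access: this sits in the PSA inner loop
  nm <- base$name; bs <- base$base; lo <- base$low; hi <- base$high
  ds <- base$dist; cl <- base$ci_lo; ch <- base$ci_hi; un <- base$units
  for (i in seq_along(vals)) {
    if (ds[i] == "fixed") next
    row <- list(name = nm[i], base = bs[i], low = lo[i], high = hi[i],
                dist = ds[i], ci_lo = cl[i], ci_hi = ch[i])
    vals[i] <- draw_one(build_sampler(row), un[i])
  }
  out <- base
  out$value <- vals
  validate_parameters(out)
  new_pdr_params(out, provenance = "psa-draw",
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Shift one parameter to a deterministic-sensitivity bound
#'
#' @param params A `pdr_params` tibble.
#' @param name Parameter to move.
#' @param bound `"low"` or `"high"`.
#' @return The modified set, tagged `"dsa-low"` / `"dsa-high"`.
#' @export
at_bound <- function(params, name, bound = c("low", "high")) {
  bound <- match.arg(bound)
  if (!name %in% params$name)
    stop("unknown parameter: ", name, call. = FALSE)
  v <- params[[bound]][params$name == name]
  params$value[params$name == name] <- v
  new_pdr_params(params, provenance = paste0("dsa-", bound))
}
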