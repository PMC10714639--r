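# Run configuration and file-producing report commands (the layer behind
# the command-line interface in inst/cli/pdrcea).

#' Default run configuration
#'
#' @param out_dir Output directory for report files.
#' @return A list of class `pdr_config` with fields: `params` (path to a
#'   YAML parameter file or `NULL` for base case), `life_table` (path to a
#'   CSV life table or `"gompertz"` for the built-in stand-in),
#'   `strategies`, `perspectives`, `comparator`, `start_age`, `end_age`,
#'   `discount_rate` (optional override), `psa_n`, `seed`, `wtp_max`,
#'   `wtp_step`, `out_dir`.
#' @export
default_run_config <- function(out_dir = "pdrcea-output") {
  structure(list(params = NULL, life_table = "gompertz",
                 strategies = pdr_strategies(),
                 perspectives = c("payer", "healthcare", "societal"),
                 comparator = "prp-only",
                 start_age = 50, end_age = 100,
                 discount_rate = NULL,
                 psa_n = 2000, seed = 1,
                 wtp_max = 100000, wtp_step = 1000,
                 out_dir = out_dir),
            class = "pdr_config")
}

#' Read a run configuration from YAML
#'
#' Keys not present keep their [default_run_config()] values; unknown keys
#' are rejected.
#'
#' @param path Path to a YAML config file.
#' @param out_dir Fallback output directory.
#' @return A validated `pdr_config` list.
#' @export
read_run_config <- function(path, out_dir = "pdrcea-output") {
  cfg <- default_run_config(out_dir)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (cfg$start_age != 50)
    stop("the model is parameterised for cohorts entering at age 50",
         call. = FALSE)
  if (cfg$end_age > 100 || cfg$end_age <= cfg$start_age)
    stop("end_age must lie in (start_age, 100]", call. = FALSE)
  if (cfg$psa_n < 1) stop("psa_n must be >= 1", call. = FALSE)
  bad <- setdiff(cfg$strategies, pdr_strategies())
  if (length(bad) > 0)
    stop("unknown strategy in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(cfg$perspectives, c("payer", "healthcare", "societal"))
  if (length(bad) > 0)
    stop("unknown perspective in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!cfg$comparator %in% cfg$strategies)
    stop("comparator must be one of the configured strategies",
         call. = FALSE)
  structure(cfg, class = "pdr_config")
}

config_inputs <- function(cfg) {
  params <- if (is.null(cfg$params)) default_parameters()
            else load_parameters(cfg$params)
  if (!is.null(cfg$discount_rate))
    params <- set_parameters(params, discount_rate = cfg$discount_rate)
  lt <- if (identical(cfg$life_table, "gompertz")) gompertz_life_table()
        else read_life_table(cfg$life_table)
  settings <- cohort_settings(start_age = cfg$start_age,
                              end_age = cfg$end_age)
  list(params = params, lt = lt, settings = settings)
}

write_metadata <- function(cfg, path) {
  meta <- list(
    package = "pdrcea",
    version = as.character(utils::packageVersion("pdrcea")),
    seed = cfg$seed,
    conventions = list(
      cycle_length_years = 1,
      rewards = "state occupied at cycle start",
      discount_exponent = "t (first cycle undiscounted)",
      half_cycle_correction = FALSE,
      currency = "2020 USD"),
    config = cfg[setdiff(names(cfg), "out_dir")])
  yaml::write_yaml(meta, path)
  path
}

#' Write the base-case incremental tables
#'
#' Runs the deterministic base case and writes, per perspective, the
#' incremental table vs the configured comparator as CSV plus a
#' human-readable text rendering, a combined strategy-results CSV, the
#' per-strategy cohort traces, and a metadata file recording the seed and
#' accounting conventions.
#'
#' @param config A `pdr_config` list (or path to a YAML config).
#' @return Invisibly, a list with the results tibble and the written file
#'   paths.
#' @export
base_case_report <- function(config = default_run_config()) {
  cfg <- if (is.character(config)) read_run_config(config) else
    validate_run_config(config)
  inp <- config_inputs(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- run_all_strategies(inp$params, inp$lt, inp$settings,
                                strategies = cfg$strategies)
  files <- character()
  for (persp in cfg$perspectives) {
    inc <- incremental_vs_comparator(results, cfg$comparator, persp)
    f_csv <- file.path(cfg$out_dir, paste0("base_case_", persp, ".csv"))
    readr::write_csv(inc, f_csv)
    f_txt <- file.path(cfg$out_dir, paste0("base_case_", persp, ".txt"))
    fmt <- format_incremental(inc)
    writeLines(c(paste0("Base case, ", persp, " perspective (vs ",
                        cfg$comparator, ")"),
                 utils::capture.output(print.data.frame(as.data.frame(fmt),
                                                        row.names = FALSE))),
               f_txt)
    files <- c(files, f_csv, f_txt)
  }
  f_res <- file.path(cfg$out_dir, "strategy_results.csv")
  readr::write_csv(results, f_res)
  for (s in cfg$strategies) {
    run <- run_cohort(s, inp$params, inp$lt, inp$settings)
    f_tr <- file.path(cfg$out_dir, paste0("trace_", s, ".csv"))
    readr::write_csv(run$trace, f_tr)
    files <- c(files, f_tr)
  }
  f_meta <- write_metadata(cfg, file.path(cfg$out_dir, "metadata.yaml"))
  invisible(list(results = results, files = c(files, f_res, f_meta)))
}

#' Write the one-way sensitivity (tornado) report
#'
#' @param config A `pdr_config` list (or path to a YAML config).
#' @param strategy,comparator Pairwise comparison for the tornado (default:
#'   configured comparator vs anti-VEGF-only, the published contrast).
#' @param plot Also write a tornado diagram (PDF)?
#' @return Invisibly, a list with the tornado tibble and file paths.
#' @export
dsa_report <- function(config = default_run_config(),
                       strategy = "antivegf-only", comparator = NULL,
                       plot = FALSE) {
  cfg <- if (is.character(config)) read_run_config(config) else
    validate_run_config(config)
  inp <- config_inputs(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  comparator <- comparator %||% cfg$comparator
  files <- character()
  for (persp in cfg$perspectives) {
    tor <- tornado(strategy = strategy, comparator = comparator,
                   perspective = persp, params = inp$params, lt = inp$lt,
                   settings = inp$settings)
    f <- file.path(cfg$out_dir, paste0("tornado_", persp, ".csv"))
    readr::write_csv(tibble::as_tibble(tor), f)
    files <- c(files, f)
    if (plot) {
      fp <- file.path(cfg$out_dir, paste0("tornado_", persp, ".pdf"))
      ggplot2::ggsave(fp, autoplot(tor), width = 8, height = 6)
      files <- c(files, fp)
    }
  }
  f_meta <- write_metadata(cfg, file.path(cfg$out_dir, "metadata_dsa.yaml"))
  invisible(list(tornado = tor, files = c(files, f_meta)))
}

#' Write the probabilistic sensitivity report
#'
#' Runs the PSA and writes the per-draw results table and, per
#' perspective, the cost-effectiveness acceptability curve CSV (WTP grid
#' by strategy probabilities); optionally CEAC plots.
#'
#' @param config A `pdr_config` list (or path to a YAML config).
#' @param plot Also write CEAC plots (PDF)?
#' @return Invisibly, a list with the `pdr_psa` object, CEAC tibbles, and
#'   file paths.
#' @export
psa_report <- function(config = default_run_config(), plot = FALSE) {
  cfg <- if (is.character(config)) read_run_config(config) else
    validate_run_config(config)
  inp <- config_inputs(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  psa <- psa_run(cfg$psa_n, seed = cfg$seed, params = inp$params,
                 lt = inp$lt, settings = inp$settings,
                 strategies = cfg$strategies)
  f_draws <- file.path(cfg$out_dir, "psa_draws.csv")
  readr::write_csv(psa$draws, f_draws)
  files <- f_draws
  grid <- seq(0, cfg$wtp_max, by = cfg$wtp_step)
  curves <- list()
  for (persp in cfg$perspectives) {
    cv <- ceac(psa, wtp_grid = grid, perspective = persp)
    curves[[persp]] <- cv
    wide <- tidyr::pivot_wider(tibble::as_tibble(cv),
                               names_from = "strategy",
                               values_from = "probability")
    f <- file.path(cfg$out_dir, paste0("ceac_", persp, ".csv"))
    readr::write_csv(wide, f)
    files <- c(files, f)
    if (plot) {
      fp <- file.path(cfg$out_dir, paste0("ceac_", persp, ".pdf"))
      ggplot2::ggsave(fp, autoplot(cv), width = 8, height = 5)
      files <- c(files, fp)
    }
  }
  f_meta <- write_metadata(cfg, file.path(cfg$out_dir, "metadata_psa.yaml"))
  invisible(list(psa = psa, ceac = curves, files = c(files, f_meta)))
}

#' Write the synthetic-data fixtures
#'
#' Generates and writes the Gompertz life-table CSV, claims-like episode
#' records with their macro-costing estimates, and EQ-5D-like survey
#' responses with their per-state utility estimates.
#'
#' @param config A `pdr_config` list (or path to a YAML config).
#' @param n_patient_years Patient-years per state for the episode records.
#' @param n_respondents Survey respondents.
#' @return Invisibly, the written file paths.
#' @export
synth_report <- function(config = default_run_config(),
                         n_patient_years = 1000, n_respondents = 300) {
  cfg <- if (is.character(config)) read_run_config(config) else
    validate_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  lt <- gompertz_life_table()
  f_lt <- file.path(cfg$out_dir, "life_table.csv")
  write_life_table(lt, f_lt)
  eps <- synth_claims_episodes(n_patient_years = n_patient_years,
                               seed = cfg$seed)
  f_eps <- file.path(cfg$out_dir, "claims_episodes.csv")
  readr::write_csv(eps, f_eps)
  f_mc <- file.path(cfg$out_dir, "macro_costing.csv")
  readr::write_csv(macro_costing(eps), f_mc)
  sv <- synth_eq5d_survey(n = n_respondents, seed = cfg$seed)
  f_sv <- file.path(cfg$out_dir, "eq5d_survey.csv")
  readr::write_csv(sv, f_sv)
  f_ut <- file.path(cfg$out_dir, "state_utilities.csv")
  readr::write_csv(estimate_state_utilities(sv), f_ut)
  invisible(c(f_lt, f_eps, f_mc, f_sv, f_ut))
}
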