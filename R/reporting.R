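#' Export model outputs to delimited and JSON reports
#'
#' Writers for the standard artefacts of an analysis run: the cohort trace
#' (cycle, state, occupancy plus per-cycle accumulators), the basecase
#' comparison (JSON and CSV mirroring the published results-table layout),
#' per-draw probabilistic results, the acceptability curve, and the
#' sensitivity grid.
#'
#' @param trace an [run_markov()] / [run_first_year()] trace object.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  occ <- trace$occupancy[seq_len(nrow(trace$cycles)), , drop = FALSE]
  long <- data.frame(cycle = rep(trace$cycles$cycle, ncol(occ)),
                     state = rep(colnames(occ), each = nrow(occ)),
                     occupancy = as.vector(occ))
  long <- merge(long, trace$cycles, by = "cycle", sort = TRUE)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param fit an [af_cea()] result.
#' @export
write_cea_csv <- function(fit, path) {
  utils::write.csv(summary(fit), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
write_cea_json <- function(fit, path) {
  x <- list(
    ablation = fit$ablation[c("expected_cost", "expected_strokes",
                              "expected_qaly")],
    aad = fit$aad[c("expected_cost", "expected_strokes", "expected_qaly")],
    incremental = list(delta_cost = fit$delta_cost,
                       delta_qaly = fit$delta_qaly,
                       delta_strokes = fit$delta_strokes,
                       icer = fit$icer, label = fit$label),
    settings = list(horizon = fit$ps$horizon,
                    discount_rate = fit$ps$discount_rate,
                    start_age = fit$profile$start_age,
                    sex = fit$profile$sex, chads2 = fit$profile$chads2))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace_csv
#' @param draws an [run_psa()] result.
#' @export
write_psa_csv <- function(draws, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", attr(draws, "seed")), con)
  utils::write.csv(as.data.frame(draws), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param curve a [ceac()] result.
#' @export
write_ceac_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param grid an [run_scenarios()] result.
#' @export
write_owsa_csv <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Config-driven commands backing the command-line interface (inst/cli/afcea).

#' Load a run configuration
#'
#' A YAML file with optional blocks `profile` (fields of [af_profile()]),
#' `parameters` (fields of [af_parameters()]), `fixtures` (paths
#' `life_table`, `event_mortality`, `utility`; omitted tables use the
#' generated stand-ins), and `options` (`n_draws`, `seed`, `wtp`).
#'
#' @param path YAML file path, or `NULL` for an all-defaults configuration.
#' @return a list of class `af_config` with `profile`, `ps`, `fixtures`,
#'   `options`.
#' @export
load_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  prof <- do.call(af_profile, raw$profile %||% list())
  ps <- do.call(af_parameters, raw$parameters %||% list())
  fx <- raw$fixtures %||% list()
  for (f in names(fx)) {
    if (!file.exists(fx[[f]])) {
      stop("fixtures file does not exist: ", f, " = ", fx[[f]],
           call. = FALSE)
    }
  }
  fixtures <- af_fixtures(
    life_table = if (is.null(fx$life_table)) make_life_table() else
      read_life_table(fx$life_table),
    event_mortality = if (is.null(fx$event_mortality))
      make_event_mortality_table() else
      read_event_mortality_table(fx$event_mortality),
    utility = if (is.null(fx$utility)) make_utility_table() else
      read_utility_table(fx$utility))
  opts <- raw$options %||% list()
  opts$n_draws <- opts$n_draws %||% 1000
  opts$seed <- opts$seed %||% 1
  opts$wtp <- opts$wtp %||% seq(0, 200000, by = 5000)
  structure(list(profile = prof, ps = ps, fixtures = fixtures,
                 options = opts),
            class = "af_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Config-driven analysis commands
#'
#' The three subcommands of the shell interface (`inst/cli/afcea`), also
#' usable directly from R: `cmd_basecase()` writes the deterministic
#' comparison (JSON + CSV + both cohort traces), `cmd_psa()` the per-draw
#' results and acceptability curve, `cmd_owsa()` the sensitivity grid. All
#' are pure functions of the configuration and seed.
#'
#' @param config an [load_run_config()] object.
#' @param out_dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
cmd_basecase <- function(config = load_run_config(), out_dir = ".") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fit <- af_cea(config$profile, config$ps, config$fixtures)
  files <- c(json = file.path(out_dir, "basecase.json"),
             csv = file.path(out_dir, "basecase.csv"),
             trace_ablation = file.path(out_dir, "trace_ablation.csv"),
             trace_aad = file.path(out_dir, "trace_aad.csv"))
  write_cea_json(fit, files["json"])
  write_cea_csv(fit, files["csv"])
  write_trace_csv(fit$ablation$trace, files["trace_ablation"])
  write_trace_csv(fit$aad$trace, files["trace_aad"])
  message("basecase: ", format_icer(fit))
  invisible(files)
}

#' @rdname cmd_basecase
#' @export
cmd_psa <- function(config = load_run_config(), out_dir = ".") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  draws <- run_psa(config$options$n_draws, seed = config$options$seed,
                   profile = config$profile, ps = config$ps,
                   fixtures = config$fixtures)
  curve <- ceac(draws, config$options$wtp)
  files <- c(draws = file.path(out_dir, "psa_draws.csv"),
             ceac = file.path(out_dir, "ceac.csv"))
  write_psa_csv(draws, files["draws"])
  write_ceac_csv(curve, files["ceac"])
  invisible(files)
}

#' @rdname cmd_basecase
#' @param specs scenario list for `cmd_owsa()` (default
#'   [builtin_scenarios()]).
#' @export
cmd_owsa <- function(config = load_run_config(), out_dir = ".",
                     specs = builtin_scenarios()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- run_scenarios(specs, config$ps, config$profile, config$fixtures)
  files <- c(owsa = file.path(out_dir, "owsa.csv"))
  write_owsa_csv(grid, files["owsa"])
  invisible(files)
}
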