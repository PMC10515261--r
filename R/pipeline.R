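#' Configure an end-to-end forecasting run
#'
#' Validates one flat key set covering every stage: load (or simulate) ->
#' optional normalize/exclude/scale -> merge -> conditional exceedance ->
#' tail fit and return-level forecast -> Gumbel baseline -> SODP QC.
#'
#' @param input Path to a long-format panel CSV, or `NULL` when `sim` is
#'   given.
#' @param sim A [sim_config()], used instead of `input`.
#' @param value_col,units,schema Passed to [load_panel()].
#' @param pop_csv Optional population CSV (columns `region`, `year`,
#'   `population`) triggering [normalize_to_percent()].
#' @param exclude Region blocklist.
#' @param limits Optional hazard limits for [scale_components()]; `NULL`
#'   keeps the panel's native units.
#' @param merge `"pointwise"` (default, synchronous annual panels) or
#'   `"interleave"`.
#' @param maxima Local-maxima mode for the interleave path.
#' @param k Conditioning number (default 3).
#' @param cut_on Tail cut-on level; `NULL` uses the 0.75 quantile of the
#'   merged values.
#' @param grid_size Number of exceedance grid levels.
#' @param return_period Forecast return period in years.
#' @param events_per_year `"auto"` (1 for pointwise, `N / span` for
#'   interleave) or a positive number.
#' @param conf Confidence level.
#' @param seed Integer seed (Gumbel bootstrap and any simulation).
#' @param out_dir Output directory.
#' @return A validated `riskcast_run_config` list.
#' @export
run_config <- function(input = NULL, sim = NULL, value_col = "Value",
                       units = "percent", schema = default_schema,
                       pop_csv = NULL, exclude = character(), limits = NULL,
                       merge = c("pointwise", "interleave"),
                       maxima = c("all_values", "strict"),
                       k = 3, cut_on = NULL, grid_size = 100,
                       return_period = 100, events_per_year = "auto",
                       conf = 0.95, seed = 1L, out_dir = tempfile("riskcast_run_")) {
  merge <- match.arg(merge)
  maxima <- match.arg(maxima)
  if (is.null(input) && is.null(sim)) {
    stop_riskcast("either 'input' or 'sim' must be given", "riskcast_config_error")
  }
  if (!is.null(sim) && !inherits(sim, "riskcast_sim_config")) {
    stop_riskcast("'sim' must be a sim_config()", "riskcast_config_error")
  }
  if (k < 1) stop_riskcast("k must be >= 1", "riskcast_config_error")
  if (return_period <= 0) stop_riskcast("return_period must be positive",
                                        "riskcast_config_error")
  if (!identical(events_per_year, "auto") &&
      (!is.numeric(events_per_year) || events_per_year <= 0)) {
    stop_riskcast("events_per_year must be \"auto\" or a positive number",
                  "riskcast_config_error")
  }
  structure(
    list(input = input, sim = sim, value_col = value_col, units = units,
         schema = schema, pop_csv = pop_csv, exclude = exclude,
         limits = limits, merge = merge, maxima = maxima, k = as.integer(k),
         cut_on = cut_on, grid_size = grid_size,
         return_period = return_period, events_per_year = events_per_year,
         conf = conf, seed = as.integer(seed), out_dir = out_dir),
    class = "riskcast_run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Flat key set mirroring [run_config()]; a `sim:` block is passed to
#' [sim_config()].
#'
#' @param path YAML file path.
#' @return A `riskcast_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$sim)) cfg$sim <- do.call(sim_config, cfg$sim)
  if (!is.null(cfg$exclude)) cfg$exclude <- as.character(cfg$exclude)
  do.call(run_config, cfg)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, riskcast_error = function(e) {
    rlang::abort(
      sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = c("riskcast_pipeline_error", "riskcast_error"),
      parent = e, stage = stage
    )
  })
}

#' Run the full forecasting pipeline
#'
#' Executes every stage of a [run_config()] and writes `merged.csv`,
#' `acer.csv`, `forecast.json`, `gumbel.json`, `sodp.csv` and a
#' human-readable `report.txt` into `cfg$out_dir`.  Identical configuration
#' and seed reproduce byte-identical numeric outputs.
#'
#' @param cfg A `riskcast_run_config`.
#' @return Invisibly, a list with the panel, merged series, exceedance
#'   function, tail fit, forecast, Gumbel baseline and SODP summary.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "riskcast_run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  panel <- with_stage("load", {
    if (!is.null(cfg$sim)) simulate_panel(cfg$sim)
    else load_panel(cfg$input, cfg$value_col, cfg$units, cfg$schema)
  })
  note("load: %d regions, years %d-%d, units=%s",
       length(panel_regions(panel)), panel_year_range(panel)[1],
       panel_year_range(panel)[2], panel$units)

  if (!is.null(cfg$pop_csv)) {
    panel <- with_stage("normalize", {
      pops <- readr::read_csv(cfg$pop_csv, show_col_types = FALSE, progress = FALSE)
      normalize_to_percent(panel, pops)
    })
    note("normalize: converted counts to percent of population")
  }
  if (length(cfg$exclude) > 0) {
    n_before <- length(panel_regions(panel))
    panel <- with_stage("exclude", exclude_regions(panel, cfg$exclude))
    note("exclude: %d -> %d regions (blocklist: %s)", n_before,
         length(panel_regions(panel)), paste(cfg$exclude, collapse = ", "))
  }
  if (!is.null(cfg$limits)) {
    panel <- with_stage("scale", scale_components(panel, cfg$limits))
    note("scale: hazard limits applied; common limit is 1 in scaled units")
  }

  merged <- with_stage("merge", {
    if (cfg$merge == "pointwise") {
      merge_pointwise_max(panel)
    } else {
      merge_interleave(extract_local_maxima(panel, cfg$maxima),
                       scaled = panel$scaled)
    }
  })
  note("merge: strategy=%s, N=%d events over %g years", cfg$merge,
       nrow(merged$data), merged$span_years)

  epy <- if (identical(cfg$events_per_year, "auto")) {
    merged$events_per_year
  } else {
    cfg$events_per_year
  }
  r <- merged_values(merged)
  cut_on <- cfg$cut_on %||% unname(stats::quantile(r, 0.75))

  acer <- with_stage("acer", estimate_acer(merged, k = cfg$k, cut_on = cut_on,
                                           grid_size = cfg$grid_size,
                                           conf = cfg$conf))
  note("acer: k=%d, cut-on %.6g, %d grid levels, %d with positive counts",
       cfg$k, cut_on, nrow(acer), sum(acer$numer > 0))

  fit <- with_stage("tail_fit", fit_tail(acer, cut_on = cut_on))
  forecast <- with_stage("predict",
                         forecast_return_level(fit, cfg$return_period, epy))
  note("predict: T=%g yr, events/yr=%.4g, level %.6g [%.6g, %.6g]",
       cfg$return_period, epy, forecast$level, forecast$ci_lo, forecast$ci_hi)

  gfit <- with_stage("gumbel", fit_gumbel(annual_block_maxima(merged), "mle"))
  glevel <- with_stage("gumbel", gumbel_return_level(gfit, cfg$return_period,
                                                     conf = cfg$conf,
                                                     seed = cfg$seed))
  note("gumbel: mu=%.6g beta=%.6g, T=%g level %.6g [%.6g, %.6g]",
       gfit$mu, gfit$beta, cfg$return_period, glevel$level, glevel$ci_lo,
       glevel$ci_hi)

  qc <- with_stage("sodp", sodp_points(merged))
  note("sodp: %d points, SD1=%.4g SD2=%.4g", qc$n, qc$sd1, qc$sd2)

  # --- outputs (deterministic formatting, no timestamps) ---
  readr::write_csv(merged$data, file.path(cfg$out_dir, "merged.csv"), progress = FALSE)
  readr::write_csv(tibble::as_tibble(acer), file.path(cfg$out_dir, "acer.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(params = fit$params, band_params = fit$band_params,
         cut_on = fit$cut_on, objective = fit$objective,
         level = forecast$level, ci = c(forecast$ci_lo, forecast$ci_hi),
         target_prob = forecast$target_prob,
         return_period = cfg$return_period, events_per_year = epy),
    file.path(cfg$out_dir, "forecast.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    list(mu = gfit$mu, beta = gfit$beta, method = gfit$method, n = gfit$n,
         level = glevel$level, ci = c(glevel$ci_lo, glevel$ci_hi),
         return_period = cfg$return_period, conf = cfg$conf),
    file.path(cfg$out_dir, "gumbel.json"), auto_unbox = TRUE, digits = NA
  )
  readr::write_csv(qc$points, file.path(cfg$out_dir, "sodp.csv"), progress = FALSE)

  report <- c(
    "riskcast pipeline report",
    "========================",
    sprintf("riskcast version: %s", as.character(utils::packageVersion("riskcast"))),
    sprintf("seed: %d", cfg$seed),
    sprintf("merge strategy: %s | maxima mode: %s", cfg$merge, cfg$maxima),
    sprintf("k: %d | cut-on: %.8g | grid size: %d", cfg$k, cut_on, cfg$grid_size),
    sprintf("return period: %g yr | events per year: %.6g | conf: %g",
            cfg$return_period, epy, cfg$conf),
    "",
    "stages:",
    paste0("  - ", log)
  )
  writeLines(report, file.path(cfg$out_dir, "report.txt"))

  invisible(list(panel = panel, merged = merged, acer = acer, tail_fit = fit,
                 forecast = forecast, gumbel_fit = gfit,
                 gumbel_forecast = glevel, sodp = qc, cut_on = cut_on,
                 events_per_year = epy, out_dir = cfg$out_dir, log = log))
}
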