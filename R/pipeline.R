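# Pipeline layer: a single structured config drives simulate -> metrics ->
# fit -> predict, each stage writing plain files so runs are reproducible
# and restartable. The thin command-line wrapper in inst/scripts/ calls
# these functions one-to-one.

.config_keys <- c("conditions", "n_cycles", "endpoint_cycle", "specimen",
                  "fitting", "geometry", "segment_factors", "jitter",
                  "seed", "out_dir")

# raw series CSVs in a directory, excluding derived per-cycle summaries
list_series_files <- function(dir) {
  f <- list.files(dir, pattern = "^series_.*\\.csv$", full.names = TRUE)
  f[!grepl("_cycles\\.csv$", f)]
}

#' Load and validate a pipeline configuration
#'
#' The configuration is one YAML (or JSON) file with keys: `conditions` (list
#' of records with `stress_variation`, `stress_rate`, optional `segment`,
#' `n_replicates`), `n_cycles`, `endpoint_cycle`, `specimen` (fields of
#' [specimen_params()]), `fitting` (`k_r`, `e_rth`, `form_id`, `beta_grid`,
#' `fit_offset`), `geometry` (`area`, `height`), `segment_factors`, `jitter`
#' (`sdlog_modulus`, `sdlog_drift`), `seed`, `out_dir`. Unknown keys are
#' rejected; omitted keys take the package defaults.
#'
#' @param path Path to the YAML/JSON config, or a named list.
#' @return A validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                     simplifyVector = TRUE)
    else yaml::read_yaml(path)
  } else if (is.list(path)) path else stop("`path` must be a file or a list")
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))

  cond <- cfg$conditions
  if (is.null(cond)) {
    cond <- standard_conditions()
  } else if (!is.data.frame(cond)) {
    cond <- do.call(rbind, lapply(cond, function(r) data.frame(
      stress_variation = r$stress_variation, stress_rate = r$stress_rate,
      segment = r$segment %||% NA_character_,
      n_replicates = as.integer(r$n_replicates %||% 3L))))
  }
  if (is.null(cond) || nrow(cond) == 0L)
    stop("config: `conditions` is empty")
  if (any(cond$n_replicates < 1L))
    stop("config: every condition needs n_replicates >= 1")

  spec <- do.call(specimen_params, cfg$specimen %||% list())
  fitting <- utils::modifyList(
    list(k_r = 1, e_rth = 0, form_id = urmk_forms()[1],
         beta_grid = c(0.02, 0.05, 0.1, 0.2, 0.5), fit_offset = TRUE),
    cfg$fitting %||% list())
  geometry <- if (!is.null(cfg$geometry))
    specimen_geometry(area = cfg$geometry$area, height = cfg$geometry$height)
  segf <- cfg$segment_factors %||% c("L5-6" = 1, "L6-7" = 0.8)
  if (is.list(segf)) segf <- unlist(segf)
  jit <- utils::modifyList(list(sdlog_modulus = 0.15, sdlog_drift = 0.2),
                           cfg$jitter %||% list())

  structure(list(conditions = cond,
                 n_cycles = cfg$n_cycles %||% 400L,
                 endpoint_cycle = cfg$endpoint_cycle %||% 400L,
                 specimen = spec, fitting = fitting, geometry = geometry,
                 segment_factors = segf, jitter = jit,
                 seed = cfg$seed %||% 1L,
                 out_dir = cfg$out_dir %||% "."),
            class = "pipeline_config")
}

config_to_list <- function(cfg) {
  list(conditions = cfg$conditions, n_cycles = cfg$n_cycles,
       endpoint_cycle = cfg$endpoint_cycle,
       specimen = params_to_list(cfg$specimen),
       fitting = cfg$fitting,
       geometry = if (!is.null(cfg$geometry))
         list(area = cfg$geometry$area, height = cfg$geometry$height),
       segment_factors = as.list(cfg$segment_factors),
       jitter = cfg$jitter, seed = cfg$seed, out_dir = cfg$out_dir)
}

#' Simulate a cohort and write it to disk
#'
#' Generates the configured cohort and writes one CSV (+ JSON sidecar) per
#' replicate, plus the resolved configuration as `config.yaml` beside the
#' outputs.
#'
#' @param config A [pipeline_config()] (or path/list accepted by it).
#' @param out_dir Output directory; default from the config.
#' @param seed Overrides the config seed when non-`NULL`.
#' @return Character vector of the CSV paths written, invisibly.
#' @export
run_simulate <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- seed %||% cfg$seed
  cohort <- generate_cohort(
    cfg$conditions, base_params = cfg$specimen, n_cycles = cfg$n_cycles,
    jitter_sdlog_modulus = cfg$jitter$sdlog_modulus,
    jitter_sdlog_drift = cfg$jitter$sdlog_drift,
    segment_factors = cfg$segment_factors, seed = seed)
  paths <- character(length(cohort))
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    p <- attr(s, "protocol")
    paths[i] <- file.path(out_dir, sprintf(
      "series_ds%04.0f_r%04.0f_%s_rep%d.csv",
      p$stress_variation * 100, p$stress_rate * 100,
      if (is.na(attr(s, "segment"))) "na" else attr(s, "segment"),
      attr(s, "replicate")))
    write_series_csv(s, paths[i])
    message(sprintf("simulated %s: %d cycles, %.3g MPa at %.3g MPa/s",
                    basename(paths[i]), p$n_cycles, p$stress_variation,
                    p$stress_rate))
  }
  resolved <- config_to_list(cfg)
  resolved$seed <- seed
  yaml::write_yaml(resolved, file.path(out_dir, "config.yaml"))
  invisible(paths)
}

#' Compute per-cycle summaries for series files
#'
#' @param inputs Character vector of series CSV paths, or a directory
#'   containing `series_*.csv`.
#' @param out_dir Output directory; defaults to the input location.
#' @param geometry Optional [specimen_geometry()] for the stiffness column.
#' @return Paths of the `*_cycles.csv` files written, invisibly.
#' @export
run_metrics <- function(inputs, out_dir = NULL, geometry = NULL) {
  if (length(inputs) == 1L && dir.exists(inputs)) {
    out_dir <- out_dir %||% inputs
    inputs <- list_series_files(inputs)
  }
  if (length(inputs) == 0L) stop("no series CSV files to process")
  out_dir <- out_dir %||% dirname(inputs[1])
  paths <- character(length(inputs))
  for (i in seq_along(inputs)) {
    s <- read_series_csv(inputs[i])
    cs <- cycle_summaries(s, geometry = geometry)
    paths[i] <- file.path(out_dir,
                          sub("\\.csv$", "_cycles.csv", basename(inputs[i])))
    write_cycle_summaries(cs, paths[i])
  }
  invisible(paths)
}

#' Fit the ratcheting model across a cohort
#'
#' Fits the saturating evolution law to the ratcheting curve of every series,
#' pools replicate fits per stress level (mean amplitude/alpha/beta across
#' replicates and rates), estimates the material coefficient K by the
#' origin-constrained amplitude-vs-X_SR regression, and fits the linear
#' evolution-parameter relations on the per-stress means.
#'
#' @param inputs Series CSV paths or a directory (as for [run_metrics()]).
#' @param config A [pipeline_config()] supplying the fitting options.
#' @param out_dir Where to write `urmk_fit.json` and `fit_report.csv`;
#'   `NULL` skips writing.
#' @return A list with `per_series` (data.frame of per-series fits), `K`,
#'   `relations` (a `urmk_relations`, or `NULL` with a warning when only one
#'   stress level is present), and `params` (a [urmk_params()] assembled from
#'   the estimates).
#' @export
run_fit <- function(inputs, config = pipeline_config(list()), out_dir = NULL) {
  if (length(inputs) == 1L && dir.exists(inputs))
    inputs <- list_series_files(inputs)
  if (length(inputs) == 0L) stop("no series CSV files to fit")
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  fo <- cfg$fitting

  rows <- lapply(inputs, function(path) {
    s <- read_series_csv(path)
    prot <- attr(s, "protocol")
    curve <- build_ratcheting_curve(s, prot)
    fit <- fit_ratcheting_curve(curve, form_id = fo$form_id,
                                beta_grid = fo$beta_grid,
                                fit_offset = fo$fit_offset)
    data.frame(file = basename(path),
               e_r = prot$stress_valley + prot$stress_variation,
               stress_rate = prot$stress_rate,
               segment = attr(s, "segment") %||% NA_character_,
               amplitude = fit$amplitude, alpha = fit$alpha, beta = fit$beta,
               offset = fit$offset, rss = fit$rss, pearson_r = fit$pearson_r,
               degenerate = fit$degenerate)
  })
  per_series <- do.call(rbind, rows)

  by_er <- split(per_series, per_series$e_r)
  pooled <- do.call(rbind, lapply(by_er, function(d) data.frame(
    e_r = d$e_r[1], amplitude = mean(d$amplitude), alpha = mean(d$alpha),
    beta = mean(d$beta))))

  K <- NULL; relations <- NULL
  if (nrow(pooled) >= 2L) {
    K <- fit_material_coefficient(pooled$amplitude, pooled$e_r,
                                  k_r = fo$k_r, e_rth = fo$e_rth)
    relations <- fit_parameter_relations(pooled$e_r, pooled$alpha,
                                         pooled$beta)
  } else {
    warning("single stress level: K and the parameter-stress relations ",
            "need >= 2 distinct stresses; per-series fits only")
  }

  params <- if (!is.null(relations)) urmk_params(
    K = K, k_r = fo$k_r, e_rth = fo$e_rth,
    alpha_intercept = relations$alpha_intercept,
    alpha_slope = relations$alpha_slope,
    beta_intercept = relations$beta_intercept,
    beta_slope = relations$beta_slope,
    form_id = fo$form_id)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(per_series, file.path(out_dir, "fit_report.csv"),
                     row.names = FALSE)
    if (!is.null(params))
      write_urmk_json(params, file.path(out_dir, "urmk_fit.json"))
  }
  list(per_series = per_series, pooled = pooled, K = K,
       relations = relations, params = params)
}

#' Predict a ratcheting curve from fitted parameters
#'
#' @param params A [urmk_params()] or a path to a JSON written by
#'   [write_urmk_json()].
#' @param e_r_new Ratcheting stress to predict at (MPa).
#' @param n_max Number of cycles to predict.
#' @param out Optional CSV path for the predicted curve.
#' @param heldout Optional [ratcheting_curve()] (or series CSV path) to
#'   overlay; the Pearson R between prediction and held-out curve is
#'   reported.
#' @param extrapolation Allowed extrapolation beyond validity (MPa band);
#'   passed to [predict_ratcheting()].
#' @return A list with `curve` (the prediction) and, when `heldout` is
#'   given, `overlay_r`.
#' @export
run_predict <- function(params, e_r_new, n_max = 400, out = NULL,
                        heldout = NULL, extrapolation = 0.3) {
  if (is.character(params)) params <- read_urmk_json(params)
  stopifnot(inherits(params, "urmk_params"))
  rel <- list(alpha_intercept = params$alpha_intercept,
              alpha_slope = params$alpha_slope,
              beta_intercept = params$beta_intercept,
              beta_slope = params$beta_slope)
  curve <- predict_ratcheting(e_r_new, seq_len(n_max), rel, K = params$K,
                              k_r = params$k_r, e_rth = params$e_rth,
                              extrapolation = extrapolation,
                              form_id = params$form_id)
  res <- list(curve = curve)
  if (!is.null(heldout)) {
    if (is.character(heldout)) {
      s <- read_series_csv(heldout)
      heldout <- build_ratcheting_curve(s)
    }
    d <- as_curve_df(heldout)
    n <- min(nrow(d), n_max)
    res$overlay_r <- stats::cor(curve$ratcheting_strain[seq_len(n)],
                                d$ratcheting_strain[seq_len(n)])
  }
  if (!is.null(out))
    utils::write.csv(as.data.frame(curve), out, row.names = FALSE)
  res
}
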