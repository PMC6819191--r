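# CSV + JSON-sidecar plumbing. Convention everywhere: compression positive
# for both stress and strain; headers carry units (`time_s,stress_MPa,strain`).

protocol_to_list <- function(p) {
  p[c("stress_variation", "stress_rate", "stress_valley", "n_cycles",
      "sampling_rate")]
}

protocol_from_list <- function(l) {
  loading_protocol(l$stress_variation, l$stress_rate, l$n_cycles,
                   sampling_rate = l$sampling_rate,
                   stress_valley = l$stress_valley %||% 0)
}

params_to_list <- function(p) {
  out <- unclass(p)
  if (!is.null(out$drift_params)) out$drift_params <-
    unclass(out$drift_params)[!vapply(out$drift_params, is.null, TRUE)]
  out[!vapply(out, is.null, TRUE)]
}

params_from_list <- function(l) {
  dp <- if (!is.null(l$drift_params)) do.call(urmk_params, l$drift_params)
  specimen_params(
    elastic_modulus_ref = l$elastic_modulus_ref,
    rate_stiffening_exponent = l$rate_stiffening_exponent,
    stress_stiffening_exponent = l$stress_stiffening_exponent,
    drift_params = dp,
    drift_rate_exponent = l$drift_rate_exponent,
    segment_factor = l$segment_factor,
    hysteresis_width = l$hysteresis_width,
    noise_sd = l$noise_sd,
    seed = l$seed)
}

#' Write a stress-strain series as CSV with a JSON metadata sidecar
#'
#' The CSV has header `time_s,stress_MPa,strain` (compression positive); the
#' sidecar `<path>.json` records the protocol, generating parameters, segment
#' label, replicate id and seed so that the record is self-describing.
#'
#' @param series A [stress_strain_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series)[, c("time_s", "stress_MPa", "strain")],
                   path, row.names = FALSE)
  meta <- list(
    convention = "compression positive",
    protocol = if (!is.null(attr(series, "protocol")))
      protocol_to_list(attr(series, "protocol")),
    params = if (!is.null(attr(series, "params")))
      params_to_list(attr(series, "params")),
    segment = attr(series, "segment"),
    replicate = attr(series, "replicate"))
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stress-strain series written by [write_series_csv()]
#'
#' @param path CSV path; the sidecar `<path>.json`, when present, restores
#'   the protocol and parameter metadata.
#' @return A [stress_strain_series()].
#' @export
read_series_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_s", "stress_MPa", "strain")
  if (!all(need %in% names(d)))
    stop("malformed series CSV: expected columns ",
         paste(need, collapse = ", "))
  if (nrow(d) == 0L) stop("empty series CSV: ", path)
  prot <- NULL; pars <- NULL; segment <- NA_character_; repl <- NA_integer_
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$protocol)) prot <- protocol_from_list(meta$protocol)
    if (!is.null(meta$params)) pars <- params_from_list(meta$params)
    segment <- meta$segment %||% NA_character_
    repl <- meta$replicate %||% NA_integer_
  }
  stress_strain_series(d$time_s, d$stress_MPa, d$strain, protocol = prot,
                       params = pars, segment = segment, replicate = repl)
}

#' Write a per-cycle summary table as CSV
#'
#' Header: `cycle,strain_min,strain_max,ratcheting_strain,strain_range,stiffness_N_per_mm`.
#'
#' @param summaries Output of [cycle_summaries()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cycle_summaries <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE)
  invisible(path)
}

#' Serialize fitted model parameters to JSON
#'
#' @param params A [urmk_params()] (units: `k_r` strain/MPa, `e_rth` MPa;
#'   `K`, `alpha`, `beta` dimensionless) or a list combining parameters with
#'   fit metadata.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_urmk_json <- function(params, path) {
  l <- if (inherits(params, "urmk_params")) {
    c(unclass(params)[!vapply(unclass(params), is.null, TRUE)],
      list(units = list(k_r = "strain/MPa", e_rth = "MPa")))
  } else params
  jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read model parameters from JSON
#'
#' @param path JSON path written by [write_urmk_json()].
#' @return A [urmk_params()].
#' @export
read_urmk_json <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  urmk_params(K = l$K, k_r = l$k_r, e_rth = l$e_rth,
              alpha = l$alpha, beta = l$beta,
              alpha_intercept = l$alpha_intercept %||% 53.565,
              alpha_slope = l$alpha_slope %||% 10.571,
              beta_intercept = l$beta_intercept %||% 0.13,
              beta_slope = l$beta_slope %||% -0.035,
              form_id = l$form_id %||% urmk_forms()[1])
}
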