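# Reference loading condition for rate/stress normalisation: the central
# stress rate of the test matrix and the smallest stress variation.
.ref_rate <- 0.59   # MPa/s
.ref_dsig <- 0.59   # MPa

# evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic disc-specimen parameters
#'
#' Mechanical parameters of the synthetic cyclic-compression response model.
#' The generated strain is
#' `strain(t) = stress(t) / E + drift(N(t)) + hysteresis(t) + noise`, where
#' the secant modulus stiffens with stress rate and stress variation as
#' `E = E_ref * (rate / 0.59)^q_rate * (dsigma / 0.59)^q_sigma`, the
#' ratcheting drift is the saturating evolution law (see [urmk_evaluate()])
#' scaled by the segment factor and attenuated with stress rate as
#' `(rate / 0.59)^(-drift_rate_exponent)`, and the hysteresis term opens the
#' loop as a half-sine per branch (positive on loading).
#'
#' @param elastic_modulus_ref Secant modulus (MPa) at the reference condition
#'   (0.59 MPa/s, 0.59 MPa), > 0.
#' @param rate_stiffening_exponent Power-law exponent of modulus vs stress
#'   rate, >= 0.
#' @param stress_stiffening_exponent Power-law exponent of modulus vs stress
#'   variation, >= 0.
#' @param drift_params A [urmk_params()] governing the ratcheting drift, or
#'   `NULL` for a drift-free (purely viscoelastic) specimen.
#' @param drift_rate_exponent Attenuation of drift with stress rate, >= 0.
#' @param segment_factor Multiplier in (0, 1] scaling the drift for more
#'   ratcheting-resistant segments (e.g. L6-7 vs L5-6).
#' @param hysteresis_width Loop opening (strain), >= 0.
#' @param noise_sd Additive Gaussian strain noise s.d., >= 0.
#' @param seed Integer seed for the noise draw; `NULL` uses the current RNG.
#' @return An object of class `specimen_params`.
#' @export
specimen_params <- function(elastic_modulus_ref = 8,
                            rate_stiffening_exponent = 0.15,
                            stress_stiffening_exponent = 0.3,
                            drift_params = urmk_params(),
                            drift_rate_exponent = 0.3,
                            segment_factor = 1,
                            hysteresis_width = 0.005,
                            noise_sd = 1e-4,
                            seed = NULL) {
  if (!is.finite(elastic_modulus_ref) || elastic_modulus_ref <= 0)
    stop("`elastic_modulus_ref` must be positive (MPa)")
  if (rate_stiffening_exponent < 0 || stress_stiffening_exponent < 0)
    stop("stiffening exponents must be >= 0")
  if (drift_rate_exponent < 0) stop("`drift_rate_exponent` must be >= 0")
  if (segment_factor <= 0 || segment_factor > 1)
    stop("`segment_factor` must lie in (0, 1]")
  if (hysteresis_width < 0) stop("`hysteresis_width` must be >= 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (!is.null(drift_params)) stopifnot(inherits(drift_params, "urmk_params"))
  structure(list(elastic_modulus_ref = elastic_modulus_ref,
                 rate_stiffening_exponent = rate_stiffening_exponent,
                 stress_stiffening_exponent = stress_stiffening_exponent,
                 drift_params = drift_params,
                 drift_rate_exponent = drift_rate_exponent,
                 segment_factor = segment_factor,
                 hysteresis_width = hysteresis_width,
                 noise_sd = noise_sd,
                 seed = seed),
            class = "specimen_params")
}

#' Stress-strain series container
#'
#' A sampled time/stress/strain record of one cyclic compression test,
#' compression positive. Metadata (protocol, specimen parameters, segment
#' label, replicate id) ride along as attributes.
#'
#' @param time_s Strictly increasing times (s).
#' @param stress_MPa Stress channel (MPa).
#' @param strain Strain channel (dimensionless).
#' @param protocol The commanding [loading_protocol()], or `NULL`.
#' @param params Generating [specimen_params()], or `NULL` for measured data.
#' @param segment Segment label (e.g. `"L5-6"`).
#' @param replicate Replicate id.
#' @return An object of classes `stress_strain_series` and `data.frame`.
#' @export
stress_strain_series <- function(time_s, stress_MPa, strain, protocol = NULL,
                                 params = NULL, segment = NA_character_,
                                 replicate = NA_integer_) {
  stopifnot(length(time_s) == length(stress_MPa),
            length(time_s) == length(strain))
  if (is.unsorted(time_s, strictly = TRUE))
    stop("`time_s` must be strictly increasing")
  structure(data.frame(time_s = time_s, stress_MPa = stress_MPa,
                       strain = strain),
            protocol = protocol, params = params, segment = segment,
            replicate = replicate,
            class = c("stress_strain_series", "data.frame"))
}

#' @export
print.stress_strain_series <- function(x, ...) {
  p <- attr(x, "protocol")
  cat(sprintf("Stress-strain series: %d samples over %.4g s%s\n", nrow(x),
              x$time_s[nrow(x)],
              if (!is.null(p)) sprintf(" (%d cycles, %.3g MPa at %.3g MPa/s)",
                                       p$n_cycles, p$stress_variation,
                                       p$stress_rate) else ""))
  if (!is.na(attr(x, "segment")))
    cat("  segment:", attr(x, "segment"), "\n")
  invisible(x)
}

#' Generate one synthetic cyclic-compression test record
#'
#' Simulates the strain response of a disc specimen to the commanded
#' triangular stress waveform. The response is the sum of
#' \itemize{
#'   \item an elastic term `stress / E` with the rate- and stress-stiffened
#'     secant modulus of [specimen_params()];
#'   \item a ratcheting drift: the saturating evolution law evaluated at the
#'     peak stress, scaled by the segment factor and the rate attenuation.
#'     The drift is constant at `drift(N)` across the loading branch of
#'     cycle `N` and ramps linearly to `drift(N + 1)` across the unloading
#'     branch (incomplete recovery), so every hysteresis loop is left
#'     unclosed by exactly the per-cycle drift increment and the per-cycle
#'     ratcheting strain equals
#'     `drift(N) + stress_variation / (2 E)`;
#'   \item a half-sine hysteresis opening per branch, positive on loading;
#'   \item i.i.d. Gaussian strain noise (stress is commanded, assumed exact).
#' }
#'
#' @param protocol A [loading_protocol()].
#' @param params A [specimen_params()].
#' @param segment,replicate Metadata labels attached to the series.
#' @return A [stress_strain_series()].
#' @export
#' @examples
#' prot <- loading_protocol(1.76, 1.18, n_cycles = 10)
#' s <- generate_response(prot, specimen_params(seed = 1))
generate_response <- function(protocol, params, segment = NA_character_,
                              replicate = NA_integer_) {
  stopifnot(inherits(protocol, "loading_protocol"),
            inherits(params, "specimen_params"))
  wf <- protocol_waveform(protocol)
  m <- protocol$samples_per_ramp
  n_cyc <- protocol$n_cycles
  E <- effective_modulus(params, protocol)

  j <- seq_len(nrow(wf)) - 1L            # 0-based global sample index
  cyc <- j %/% (2L * m) + 1L             # cycle each sample belongs to
  k <- j %% (2L * m)                     # within-cycle sample index

  drift <- if (is.null(params$drift_params)) {
    numeric(nrow(wf))
  } else {
    dr <- drift_curve(params, protocol, n_max = n_cyc + 1L)
    unload_frac <- pmax(0, (k - m) / m)  # 0 on loading, ramps 0..1 unloading
    dr[cyc] + unload_frac * (dr[pmin(cyc + 1L, n_cyc + 1L)] - dr[cyc])
  }

  hyst <- params$hysteresis_width * sin(2 * pi * k / (2 * m))

  noise <- if (params$noise_sd > 0) {
    with_seed(params$seed, stats::rnorm(nrow(wf), 0, params$noise_sd))
  } else numeric(nrow(wf))

  stress_strain_series(
    time_s = wf$time_s, stress_MPa = wf$stress_MPa,
    strain = wf$stress_MPa / E + drift + hyst + noise,
    protocol = protocol, params = params,
    segment = segment, replicate = replicate)
}

# secant modulus at a protocol's rate and stress variation
effective_modulus <- function(params, protocol) {
  params$elastic_modulus_ref *
    (protocol$stress_rate / .ref_rate)^params$rate_stiffening_exponent *
    (protocol$stress_variation / .ref_dsig)^params$stress_stiffening_exponent
}

# ratcheting drift at cycles 1..n_max for a specimen under a protocol
drift_curve <- function(params, protocol, n_max = protocol$n_cycles) {
  if (is.null(params$drift_params)) return(numeric(n_max))
  e_r <- protocol$stress_valley + protocol$stress_variation
  scale <- params$segment_factor *
    (protocol$stress_rate / .ref_rate)^(-params$drift_rate_exponent)
  scale * urmk_evaluate(seq_len(n_max), e_r, params$drift_params)
}

#' Build the standard loading-condition matrix
#'
#' The ten-condition test matrix used for sheep lumbar discs: stress
#' variations 0.59-1.76 MPa crossed with stress rates 0.13-1.18 MPa/s, with
#' the stress valley fixed at 0 MPa.
#'
#' @param n_replicates Replicates per condition (the protocol calls for at
#'   least three).
#' @return A data.frame with columns `specimen_type`, `stress_variation`,
#'   `stress_rate`, `segment`, `n_replicates`.
#' @export
standard_conditions <- function(n_replicates = 3) {
  data.frame(
    specimen_type = c(rep("L1-L4", 3), rep("L4-L7", 4), rep("L1-L4", 3)),
    stress_variation = c(0.59, 0.59, 0.59, 0.59, 0.88, 1.18, 1.76,
                         1.76, 1.76, 1.76),
    stress_rate = c(0.13, 0.4, 1.18, 0.59, 0.59, 0.59, 0.59,
                    0.4, 0.59, 1.18),
    segment = NA_character_,
    n_replicates = as.integer(n_replicates)
  )
}

#' Generate a cohort of synthetic test records
#'
#' Simulates every condition of a loading matrix with replicate-level
#' biological variability: log-normal multiplicative jitter on the secant
#' modulus and on the drift amplitude (the material coefficient K), keeping
#' both positive. Per-series seeds are derived deterministically from the
#' cohort seed and the condition/replicate indices.
#'
#' @param conditions A data.frame with columns `stress_variation`,
#'   `stress_rate`, and optionally `segment` and `n_replicates`; see
#'   [standard_conditions()].
#' @param base_params The cohort-level [specimen_params()].
#' @param n_cycles Cycles per test (default 400).
#' @param n_replicates Default replicate count for conditions lacking one.
#' @param jitter_sdlog_modulus,jitter_sdlog_drift Log-scale s.d. of the
#'   replicate jitter on modulus and drift amplitude; 0 disables jitter.
#' @param segment_factors Named numeric vector mapping segment labels to
#'   drift scale factors, e.g. `c("L5-6" = 1, "L6-7" = 0.8)`.
#' @param seed Cohort seed (integer).
#' @return A list of [stress_strain_series()], one per replicate, each tagged
#'   with its condition metadata; the conditions table is attached as
#'   attribute `conditions`.
#' @export
generate_cohort <- function(conditions, base_params = specimen_params(),
                            n_cycles = 400, n_replicates = 3,
                            jitter_sdlog_modulus = 0.15,
                            jitter_sdlog_drift = 0.2,
                            segment_factors = c("L5-6" = 1, "L6-7" = 0.8),
                            seed = 1) {
  if (!is.data.frame(conditions) || nrow(conditions) == 0L)
    stop("`conditions` must be a non-empty data.frame")
  if (is.null(conditions$segment)) conditions$segment <- NA_character_
  if (is.null(conditions$n_replicates))
    conditions$n_replicates <- as.integer(n_replicates)
  if (any(conditions$n_replicates < 1L))
    stop("every condition needs at least one replicate")

  out <- list()
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    prot <- loading_protocol(cond$stress_variation, cond$stress_rate,
                             n_cycles = n_cycles)
    seg_fac <- if (!is.na(cond$segment) && cond$segment %in%
                   names(segment_factors)) {
      unname(segment_factors[cond$segment])
    } else base_params$segment_factor
    for (ri in seq_len(cond$n_replicates)) {
      series_seed <- (seed + 7919L * ci + 104729L * ri) %% 2147483647L
      mult <- with_seed(series_seed, stats::rlnorm(2, 0, c(
        jitter_sdlog_modulus, jitter_sdlog_drift)))
      dp <- base_params$drift_params
      if (!is.null(dp)) dp$K <- dp$K * mult[2]
      p <- base_params
      p$elastic_modulus_ref <- base_params$elastic_modulus_ref * mult[1]
      p$drift_params <- dp
      p$segment_factor <- seg_fac
      p$seed <- (series_seed + 1L) %% 2147483647L
      out[[length(out) + 1L]] <- generate_response(
        prot, p, segment = cond$segment, replicate = ri)
    }
  }
  attr(out, "conditions") <- conditions
  out
}
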