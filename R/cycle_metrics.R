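#' Per-cycle ratcheting strain
#'
#' The ratcheting strain of one cycle is the mean of its valley and peak
#' strains, `eps_r = (eps_min + eps_max) / 2`: the centre of the hysteresis
#' loop, whose cycle-by-cycle drift is the ratcheting accumulation.
#'
#' @param strain_min Valley strain of the cycle (dimensionless). Vectorised.
#' @param strain_max Peak strain of the cycle; must satisfy
#'   `strain_min <= strain_max` elementwise.
#' @return `(strain_min + strain_max) / 2`.
#' @export
ratcheting_strain <- function(strain_min, strain_max) {
  if (any(strain_min > strain_max))
    stop("`strain_min` must not exceed `strain_max`")
  (strain_min + strain_max) / 2
}

#' Ratcheting curve container
#'
#' Per-cycle ratcheting metrics of one test: cycle indices (1-based),
#' ratcheting strain, and optionally the per-cycle ratcheting rate, together
#' with the loading-condition metadata.
#'
#' @param cycle Strictly increasing 1-based cycle indices.
#' @param ratcheting_strain Per-cycle ratcheting strain.
#' @param ratcheting_rate Optional per-cycle rate (strain per cycle).
#' @param stress_variation,stress_rate,segment Condition metadata.
#' @return An object of classes `ratcheting_curve` and `data.frame`.
#' @export
ratcheting_curve <- function(cycle, ratcheting_strain, ratcheting_rate = NULL,
                             stress_variation = NA_real_,
                             stress_rate = NA_real_,
                             segment = NA_character_) {
  stopifnot(length(cycle) == length(ratcheting_strain))
  if (is.unsorted(cycle, strictly = TRUE))
    stop("`cycle` must be strictly increasing")
  d <- data.frame(cycle = cycle, ratcheting_strain = ratcheting_strain)
  if (!is.null(ratcheting_rate)) {
    stopifnot(length(ratcheting_rate) == length(cycle))
    d$ratcheting_rate <- ratcheting_rate
  }
  structure(d, stress_variation = stress_variation,
            stress_rate = stress_rate, segment = segment,
            class = c("ratcheting_curve", "data.frame"))
}

# accept a ratcheting_curve, data.frame, or bare list with cycle + strain
as_curve_df <- function(curve) {
  if (is.list(curve) && !is.null(curve$cycle) &&
      !is.null(curve$ratcheting_strain))
    return(data.frame(cycle = curve$cycle,
                      ratcheting_strain = curve$ratcheting_strain))
  stop("`curve` must have components `cycle` and `ratcheting_strain`")
}

#' @export
print.ratcheting_curve <- function(x, ...) {
  cat(sprintf(
    "Ratcheting curve: %d cycles (delta-sigma = %s MPa, rate = %s MPa/s%s)\n",
    nrow(x), format(attr(x, "stress_variation")),
    format(attr(x, "stress_rate")),
    if (!is.na(attr(x, "segment"))) paste0(", ", attr(x, "segment")) else ""))
  cat(sprintf("  ratcheting strain: %.6g (cycle %d) -> %.6g (cycle %d)\n",
              x$ratcheting_strain[1], x$cycle[1],
              x$ratcheting_strain[nrow(x)], x$cycle[nrow(x)]))
  invisible(x)
}

#' Per-cycle ratcheting strain rate
#'
#' The ratcheting strain rate is the increment of ratcheting strain per unit
#' cycle, `d(eps_r)/dN`, computed by central finite differences in the cycle
#' index (one-sided at the two ends).
#'
#' @param curve A [ratcheting_curve()] (or anything with `cycle` and
#'   `ratcheting_strain`), with at least 2 cycles.
#' @return Numeric vector of rates, one per cycle.
#' @export
ratcheting_rate <- function(curve) {
  d <- as_curve_df(curve)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 cycles to compute a ratcheting rate")
  y <- d$ratcheting_strain
  N <- d$cycle
  rate <- numeric(n)
  rate[1] <- (y[2] - y[1]) / (N[2] - N[1])
  rate[n] <- (y[n] - y[n - 1]) / (N[n] - N[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    rate[i] <- (y[i + 1] - y[i - 1]) / (N[i + 1] - N[i - 1])
  }
  rate
}

#' Segment a cyclic record into complete cycles
#'
#' Splits a stress-strain series into valley-to-valley cycles of the
#' commanded protocol. Cycle boundaries are placed on the commanded time grid
#' (`t = (N - 1) * period`); a trailing partial cycle is discarded.
#'
#' @param series A [stress_strain_series()] (or data.frame with `time_s`).
#' @param protocol The [loading_protocol()] the series was commanded with.
#'   `NULL` uses the protocol stored in the series metadata.
#' @return A data.frame with one row per complete cycle: `cycle`, `start`,
#'   `peak`, `end` (sample indices of the starting valley, the peak, and the
#'   closing valley).
#' @export
segment_cycles <- function(series, protocol = NULL) {
  if (is.null(protocol)) protocol <- attr(series, "protocol")
  stopifnot(inherits(protocol, "loading_protocol"))
  time <- series$time_s
  if (length(time) < 2L) stop("segmentation error: series too short")
  dt_obs <- stats::median(diff(time))
  spc <- protocol$period / dt_obs          # samples per cycle, observed
  spc_int <- round(spc)
  if (spc_int < 4L || abs(spc - spc_int) > 1e-6 * spc)
    stop("segmentation error: series time stamps are inconsistent with the ",
         "protocol period (", signif(protocol$period, 6), " s vs observed ",
         signif(spc * dt_obs, 6), " s)")
  n_complete <- floor((length(time) - 1L) / spc_int)
  n_complete <- min(n_complete, protocol$n_cycles)
  if (n_complete < 1L)
    stop("segmentation error: series does not cover one full cycle")
  start <- (seq_len(n_complete) - 1L) * spc_int + 1L
  data.frame(cycle = seq_len(n_complete),
             start = start,
             peak  = start + spc_int %/% 2L,
             end   = start + spc_int)
}

#' Compression stiffness of one cycle
#'
#' Secant stiffness of the loading branch in machine units:
#' `(F_peak - F_valley) / (d_peak - d_valley)` with force `F = sigma * S` (N)
#' and displacement `d = eps * h` (mm). This peak-to-valley secant is the
#' standard machine-log convention and is robust to the hysteresis-loop shape.
#'
#' @param series A [stress_strain_series()].
#' @param geometry A [specimen_geometry()].
#' @param cycle Cycle number to evaluate (default 400).
#' @param protocol Protocol; `NULL` uses the series metadata.
#' @return Stiffness (N/mm).
#' @export
compression_stiffness <- function(series, geometry, cycle = 400,
                                  protocol = NULL) {
  stopifnot(inherits(geometry, "specimen_geometry"))
  seg <- segment_cycles(series, protocol)
  if (cycle > nrow(seg))
    stop("series has only ", nrow(seg), " complete cycles; cannot evaluate ",
         "stiffness at cycle ", cycle)
  row <- seg[seg$cycle == cycle, ]
  i_v <- row$start
  i_p <- row$peak
  dF <- (series$stress_MPa[i_p] - series$stress_MPa[i_v]) * geometry$area
  dd <- (series$strain[i_p] - series$strain[i_v]) * geometry$height
  if (abs(dd) < .Machine$double.eps * 100)
    stop("degenerate cycle: zero displacement span over the loading branch")
  dF / dd
}

#' Per-cycle summary table of a cyclic test
#'
#' Applies [segment_cycles()] and computes, for every complete cycle, the
#' valley strain (taken at the commanded stress-valley sample that opens the
#' cycle), the peak strain (at the commanded peak sample), the ratcheting
#' strain, the strain range, and (when geometry is supplied) the loading
#' secant compression stiffness.
#'
#' @inheritParams compression_stiffness
#' @param geometry Optional [specimen_geometry()]; without it the stiffness
#'   column is `NA`.
#' @return A data.frame with columns `cycle`, `strain_min`, `strain_max`,
#'   `ratcheting_strain`, `strain_range`, `stiffness_N_per_mm`.
#' @export
cycle_summaries <- function(series, protocol = NULL, geometry = NULL) {
  if (is.null(protocol)) protocol <- attr(series, "protocol")
  seg <- segment_cycles(series, protocol)
  s_min <- series$strain[seg$start]
  s_max <- series$strain[seg$peak]
  stiff <- if (!is.null(geometry)) {
    dF <- (series$stress_MPa[seg$peak] - series$stress_MPa[seg$start]) *
      geometry$area
    dd <- (s_max - s_min) * geometry$height
    ifelse(abs(dd) < .Machine$double.eps * 100, NA_real_, dF / dd)
  } else NA_real_
  data.frame(cycle = seg$cycle,
             strain_min = s_min,
             strain_max = s_max,
             ratcheting_strain = ratcheting_strain(pmin(s_min, s_max),
                                                   pmax(s_min, s_max)),
             strain_range = s_max - s_min,
             stiffness_N_per_mm = stiff)
}

#' Extract the ratcheting curve of a test record
#'
#' Composition of [segment_cycles()], [cycle_summaries()] and
#' [ratcheting_rate()]: the full per-cycle ratcheting analysis of one series.
#'
#' @inheritParams cycle_summaries
#' @return A [ratcheting_curve()] carrying `ratcheting_rate` and the
#'   condition metadata of the series.
#' @export
build_ratcheting_curve <- function(series, protocol = NULL, geometry = NULL) {
  if (is.null(protocol)) protocol <- attr(series, "protocol")
  cs <- cycle_summaries(series, protocol, geometry)
  rc <- ratcheting_curve(
    cycle = cs$cycle,
    ratcheting_strain = cs$ratcheting_strain,
    stress_variation = if (!is.null(protocol)) protocol$stress_variation
                       else NA_real_,
    stress_rate = if (!is.null(protocol)) protocol$stress_rate else NA_real_,
    segment = attr(series, "segment") %||% NA_character_)
  rc$ratcheting_rate <- if (nrow(cs) >= 2L) ratcheting_rate(rc) else NA_real_
  rc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
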