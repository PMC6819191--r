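#' Build a stress-controlled triangular loading protocol
#'
#' Constructs the commanded stress waveform of a stress-controlled cyclic
#' compression test: a piecewise-linear triangular wave that starts each cycle
#' at the stress valley, reaches the peak at mid-cycle, and returns to the
#' valley. The cycle period is `2 * stress_variation / stress_rate`.
#'
#' Compression is taken positive for both stress and strain throughout the
#' package. The sampling interval is snapped so that an integer number of
#' samples falls on each ramp; valley and peak samples therefore hit the
#' commanded extrema exactly.
#'
#' @param stress_variation Peak-to-valley stress amplitude (MPa), > 0. With a
#'   0 MPa valley this equals the peak stress.
#' @param stress_rate Magnitude of the commanded stress rate (MPa/s), > 0.
#' @param n_cycles Number of complete cycles, >= 1.
#' @param sampling_rate Sampling frequency (Hz). `NULL` (default) chooses the
#'   rate that places 40 samples on each ramp. Must place at least 20 samples
#'   per ramp.
#' @param stress_valley Valley stress (MPa). Default 0, the protocol used for
#'   disc testing.
#'
#' @return An object of class `loading_protocol`: a list with the arguments
#'   plus `period` (s), `ramp_duration` (s), `samples_per_ramp`, and `dt` (s).
#' @seealso [protocol_waveform()] to sample the commanded stress channel.
#' @export
#' @examples
#' p <- loading_protocol(1.76, 1.18, n_cycles = 200)
#' p$period  # 2 * 1.76 / 1.18 ~ 2.983 s
loading_protocol <- function(stress_variation, stress_rate, n_cycles,
                             sampling_rate = NULL, stress_valley = 0) {
  stopifnot(is.numeric(stress_variation), is.numeric(stress_rate),
            is.numeric(n_cycles), length(stress_variation) == 1L,
            length(stress_rate) == 1L, length(n_cycles) == 1L)
  if (!is.finite(stress_variation) || stress_variation <= 0)
    stop("invalid protocol: `stress_variation` must be a positive stress (MPa)")
  if (!is.finite(stress_rate) || stress_rate <= 0)
    stop("invalid protocol: `stress_rate` must be positive (MPa/s)")
  if (!is.finite(n_cycles) || n_cycles < 1 || n_cycles != round(n_cycles))
    stop("invalid protocol: `n_cycles` must be a positive integer")
  if (!is.finite(stress_valley) || stress_valley < 0)
    stop("invalid protocol: `stress_valley` must be non-negative (MPa)")

  ramp_duration <- stress_variation / stress_rate
  if (is.null(sampling_rate)) sampling_rate <- 40 / ramp_duration
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop("invalid protocol: `sampling_rate` must be positive (Hz)")

  samples_per_ramp <- floor(sampling_rate * ramp_duration)
  if (samples_per_ramp < 20)
    stop("sampling too coarse: fewer than 20 samples per loading ramp ",
         "(got ", samples_per_ramp, "); increase `sampling_rate`")

  structure(list(
    stress_variation = stress_variation,
    stress_rate      = stress_rate,
    stress_valley    = stress_valley,
    n_cycles         = as.integer(n_cycles),
    sampling_rate    = sampling_rate,
    ramp_duration    = ramp_duration,
    period           = 2 * ramp_duration,
    samples_per_ramp = samples_per_ramp,
    dt               = ramp_duration / samples_per_ramp
  ), class = "loading_protocol")
}

#' @export
print.loading_protocol <- function(x, ...) {
  cat("Triangular loading protocol (compression positive)\n")
  cat(sprintf("  stress: %.3g -> %.3g MPa at %.3g MPa/s\n",
              x$stress_valley, x$stress_valley + x$stress_variation,
              x$stress_rate))
  cat(sprintf("  %d cycles, period %.4g s, %d samples/ramp (dt = %.4g s)\n",
              x$n_cycles, x$period, x$samples_per_ramp, x$dt))
  invisible(x)
}

#' Sample the commanded stress waveform of a protocol
#'
#' @param protocol A [loading_protocol()].
#' @return A data.frame with columns `time_s` and `stress_MPa` covering all
#'   `n_cycles` cycles, endpoint included; valley and peak samples are exact.
#' @export
protocol_waveform <- function(protocol) {
  stopifnot(inherits(protocol, "loading_protocol"))
  n_samp <- 2L * protocol$samples_per_ramp * protocol$n_cycles
  time <- seq(0, by = protocol$dt, length.out = n_samp + 1L)
  data.frame(time_s = time, stress_MPa = commanded_stress(time, protocol))
}

#' Commanded triangular stress at given times
#'
#' @param time Numeric vector of times (s).
#' @param protocol A [loading_protocol()].
#' @return Stress (MPa) at each time.
#' @keywords internal
#' @export
commanded_stress <- function(time, protocol) {
  phase <- (time %% protocol$period) / protocol$period
  tri <- ifelse(phase <= 0.5, 2 * phase, 2 * (1 - phase))
  protocol$stress_valley + protocol$stress_variation * tri
}

#' Elliptic disc area from measured length and width
#'
#' The transverse cross-section of an intervertebral disc is close to an
#' ellipse with the measured length and width as its axes, so the area is
#' `(pi/4) * length * width`, multiplied by an empirical shape coefficient
#' `k` (1.01 for sheep lumbar discs) that absorbs the deviation from a true
#' ellipse.
#'
#' @param length Disc length (mm), > 0.
#' @param width Disc width (mm), > 0.
#' @param k Dimensionless area coefficient, > 0. Default 1.01.
#' @return Disc area (mm^2).
#' @export
#' @examples
#' area_from_dims(25, 20)  # ~396.6 mm^2
area_from_dims <- function(length, width, k = 1.01) {
  if (any(!is.finite(c(length, width, k))) || any(c(length, width, k) <= 0))
    stop("`length`, `width` and `k` must all be positive")
  (pi / 4) * length * width * k
}

#' Specimen geometry of a disc sample
#'
#' Holds the quantities needed to convert between engineering stress/strain
#' and machine force/displacement: cross-sectional area `S` (mm^2) and disc
#' height `h` (mm). Area may be given directly or computed from length and
#' width via [area_from_dims()].
#'
#' @param area Disc area S (mm^2). If `NULL`, computed from `length`/`width`.
#' @param height Disc height h (mm), > 0.
#' @param length,width Disc dimensions (mm), used when `area` is `NULL`.
#' @param area_coefficient Shape coefficient k, default 1.01.
#' @return An object of class `specimen_geometry`.
#' @export
#' @examples
#' specimen_geometry(area = 394, height = 3.98)
specimen_geometry <- function(area = NULL, height, length = NULL, width = NULL,
                              area_coefficient = 1.01) {
  if (is.null(area)) {
    if (is.null(length) || is.null(width))
      stop("provide `area`, or both `length` and `width`")
    area <- area_from_dims(length, width, area_coefficient)
  }
  if (!is.finite(area) || area <= 0) stop("`area` must be positive (mm^2)")
  if (!is.finite(height) || height <= 0) stop("`height` must be positive (mm)")
  structure(list(area = area, height = height,
                 length = length, width = width,
                 area_coefficient = area_coefficient),
            class = "specimen_geometry")
}

#' @export
print.specimen_geometry <- function(x, ...) {
  cat(sprintf("Disc specimen geometry: S = %.4g mm^2, h = %.4g mm\n",
              x$area, x$height))
  invisible(x)
}
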