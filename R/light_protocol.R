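#' Piecewise-constant light protocols
#'
#' A light protocol is an ordered set of segments, each switching the ambient
#' blue-light intensity to a new constant value at a given time. Time is in
#' minutes with t = 0 at the first light-on event; intensity is in
#' umol photons m^-2 s^-1. Before the first segment the intensity is 0
#' (dark pre-incubation).
#'
#' @param start_time numeric vector of segment start times (minutes),
#'   strictly increasing.
#' @param intensity numeric vector of intensities (umol m^-2 s^-1), same
#'   length as `start_time`, all >= 0.
#' @return An object of class `light_protocol`: a data.frame with columns
#'   `start_time` and `intensity`.
#' @examples
#' p <- light_protocol(c(0, 300, 1000), c(2, 20, 200))
#' intensity_at(p, c(-60, 100, 400, 1100))
#' @export
light_protocol <- function(start_time = numeric(0), intensity = numeric(0)) {
  start_time <- as.numeric(start_time)
  intensity <- as.numeric(intensity)
  if (length(start_time) != length(intensity))
    stop("start_time and intensity must have the same length")
  if (length(start_time) > 1 && any(diff(start_time) <= 0))
    stop("segment start times must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  structure(data.frame(start_time = start_time, intensity = intensity),
            class = c("light_protocol", "data.frame"))
}

#' @export
print.light_protocol <- function(x, ...) {
  cat("Light protocol (", nrow(x), " segment",
      if (nrow(x) != 1) "s", ")\n", sep = "")
  if (nrow(x) > 0) {
    for (i in seq_len(nrow(x)))
      cat(sprintf("  t >= %6g min : %g umol m-2 s-1\n",
                  x$start_time[i], x$intensity[i]))
  } else cat("  constant darkness\n")
  invisible(x)
}

#' Light intensity at given times
#'
#' Looks up the piecewise-constant intensity: the value of the last segment
#' whose start time is <= t, and 0 before the first segment (or for an
#' empty protocol).
#'
#' @param protocol a [light_protocol()].
#' @param t numeric vector of times (minutes).
#' @return Numeric vector of intensities, same length as `t`.
#' @export
intensity_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "light_protocol"))
  if (nrow(protocol) == 0) return(rep(0, length(t)))
  idx <- findInterval(t, protocol$start_time)
  ifelse(idx == 0, 0, protocol$intensity[pmax(idx, 1)])
}

#' The three-step light-induction protocol
#'
#' Dark-grown cultures are exposed to 2 umol m^-2 s^-1 at t = 0, stepped to
#' 20 at t = 300 min and to 200 at t = 1000 min — the logarithmic
#' dim-light-to-cloudy-day staircase used for model calibration.
#'
#' @return A [light_protocol()].
#' @export
lightstep_protocol <- function() {
  light_protocol(c(0, 300, 1000), c(2, 20, 200))
}

#' Two-pulse protocol for refractory-period experiments
#'
#' Two identical light pulses separated by a dark interval, used to probe
#' the refractory phase of the photosystem.
#'
#' @param dark_interval dark gap between the pulses (minutes).
#' @param pulse_intensity pulse light level (umol m^-2 s^-1), default 20.
#' @param pulse_duration pulse length (minutes), default 30.
#' @return A [light_protocol()] with the first pulse starting at t = 0.
#' @export
two_pulse_protocol <- function(dark_interval, pulse_intensity = 20,
                               pulse_duration = 30) {
  stopifnot(dark_interval > 0, pulse_duration > 0, pulse_intensity >= 0)
  light_protocol(
    c(0, pulse_duration,
      pulse_duration + dark_interval, 2 * pulse_duration + dark_interval),
    c(pulse_intensity, 0, pulse_intensity, 0))
}

#' Constant-light protocol
#'
#' @param intensity constant light level from t = 0 on.
#' @param lights_off optional time (minutes) at which light is switched off
#'   (for light-to-dark transfer experiments); `NULL` for constant light.
#' @return A [light_protocol()].
#' @export
constant_light_protocol <- function(intensity, lights_off = NULL) {
  if (is.null(lights_off)) light_protocol(0, intensity)
  else light_protocol(c(0, lights_off), c(intensity, 0))
}
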