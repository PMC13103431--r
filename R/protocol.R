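#' Build an illumination protocol
#'
#' An `npq_protocol` couples an ordered sequence of actinic light phases with
#' a saturating-pulse (SP) schedule. Phases are contiguous, non-overlapping
#' half-open intervals `[start, start + duration)`; the SP schedule defines
#' the sampling grid of the per-cell Fm' trace (one sample per pulse).
#'
#' @param phases A data frame with one row per phase and columns `label`
#'   (one of `"HL"`, `"LOW"`, `"DARK"`), `duration` (s, > 0), `intensity`
#'   (umol photons m^-2 s^-1, >= 0) and optionally `wavelength` (nm, `NA`
#'   for dark phases). Phase start times are derived by cumulation.
#' @param pulse_period Seconds between consecutive saturating pulses.
#' @param pulse_duration Duration of one pulse (s); must be `< pulse_period`.
#' @param pulse_intensity Pulse intensity (umol photons m^-2 s^-1).
#' @param pulse_wavelength Pulse wavelength (nm).
#'
#' @return An object of class `npq_protocol`: a list with elements `phases`
#'   (a tibble with `label`, `start`, `duration`, `intensity`, `wavelength`),
#'   `pulses` (a list with `period`, `duration`, `intensity`, `wavelength`)
#'   and `total_duration` (s).
#' @seealso [reference_protocol()], [pulse_times()], [phase_at()]
#' @export
#' @examples
#' p <- npq_protocol(
#'   data.frame(label = c("HL", "DARK"), duration = c(900, 900),
#'              intensity = c(400, 0), wavelength = c(470, NA)),
#'   pulse_period = 20
#' )
#' length(pulse_times(p))
npq_protocol <- function(phases,
                         pulse_period = 20,
                         pulse_duration = 0.2,
                         pulse_intensity = 1400,
                         pulse_wavelength = 405) {
  phases <- tibble::as_tibble(phases)
  required <- c("label", "duration", "intensity")
  if (!all(required %in% names(phases))) {
    stop("`phases` must have columns label, duration, intensity", call. = FALSE)
  }
  if (!"wavelength" %in% names(phases)) phases$wavelength <- NA_real_
  if (!all(phases$label %in% c("HL", "LOW", "DARK"))) {
    stop("phase labels must be one of 'HL', 'LOW', 'DARK'", call. = FALSE)
  }
  if (any(phases$duration <= 0)) stop("phase durations must be > 0", call. = FALSE)
  if (any(phases$intensity < 0)) stop("phase intensities must be >= 0", call. = FALSE)
  if (any(phases$label == "DARK" & phases$intensity != 0)) {
    stop("DARK phases must have zero intensity", call. = FALSE)
  }
  if (pulse_period <= 0) stop("pulse_period must be > 0", call. = FALSE)
  if (pulse_duration >= pulse_period) {
    stop("pulse_duration must be smaller than pulse_period", call. = FALSE)
  }
  phases <- dplyr::mutate(phases,
    start = cumsum(dplyr::lag(.data$duration, default = 0))
  )
  phases <- dplyr::select(phases, "label", "start", "duration", "intensity", "wavelength")
  structure(
    list(
      phases = phases,
      pulses = list(
        period = pulse_period, duration = pulse_duration,
        intensity = pulse_intensity, wavelength = pulse_wavelength
      ),
      total_duration = sum(phases$duration)
    ),
    class = "npq_protocol"
  )
}

#' Reference high-light / dark protocol
#'
#' The reference protocol used throughout: 15 min of high light
#' (400 umol photons m^-2 s^-1, 470 nm) followed by 15 min of darkness,
#' with saturating pulses every 20 s (1400 umol photons m^-2 s^-1, 405 nm,
#' 200 ms), the first pulse at t = 0. Over the 1800 s this yields 91 pulses,
#' hence 91-point Fm' traces.
#'
#' @return An [npq_protocol()] object.
#' @export
#' @examples
#' length(pulse_times(reference_protocol()))  # 91
reference_protocol <- function() {
  npq_protocol(
    data.frame(
      label = c("HL", "DARK"),
      duration = c(900, 900),
      intensity = c(400, 0),
      wavelength = c(470, NA)
    ),
    pulse_period = 20, pulse_duration = 0.2,
    pulse_intensity = 1400, pulse_wavelength = 405
  )
}

#' Saturating-pulse sampling times of a protocol
#'
#' Pulses fire at `t = k * period` for `k = 0, 1, ...` while `t` does not
#' exceed the protocol's total duration, so a protocol of duration `T`
#' carries `floor(T / period) + 1` pulses.
#'
#' @param protocol An [npq_protocol()].
#' @return Strictly increasing numeric vector of pulse times in seconds.
#' @export
pulse_times <- function(protocol) {
  stopifnot(inherits(protocol, "npq_protocol"))
  period <- protocol$pulses$period
  seq(0, protocol$total_duration, by = period)
}

#' Actinic phase active at a given time
#'
#' Phases are half-open `[start, start + duration)`: a time exactly at a
#' phase boundary belongs to the incoming phase (a pulse at the light-to-dark
#' transition samples the dark phase). The final instant of the protocol maps
#' to the last phase.
#'
#' @param protocol An [npq_protocol()].
#' @param t Time in seconds, `0 <= t <= total duration`.
#' @return A one-row tibble (the matching row of `protocol$phases`).
#' @export
phase_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "npq_protocol"))
  if (t < 0 || t > protocol$total_duration) {
    stop("t = ", t, " outside protocol [0, ", protocol$total_duration, "]",
         call. = FALSE)
  }
  ph <- protocol$phases
  if (t == protocol$total_duration) return(ph[nrow(ph), ])
  idx <- which(t >= ph$start & t < ph$start + ph$duration)
  ph[idx[1], ]
}

#' @export
print.npq_protocol <- function(x, ...) {
  cat("<npq_protocol> total", x$total_duration, "s,",
      nrow(x$phases), "phases,",
      length(pulse_times(x)), "pulses (period", x$pulses$period, "s)\n")
  print(x$phases)
  invisible(x)
}

#' Read / write a protocol as a YAML config
#'
#' The file stores the phase table and the pulse block with units seconds
#' and umol photons m^-2 s^-1 (stated in a header comment on write).
#'
#' @param protocol An [npq_protocol()].
#' @param path File path.
#' @return `write_protocol()` returns `path` invisibly; `read_protocol()`
#'   returns an [npq_protocol()].
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "npq_protocol"))
  obj <- list(
    phases = purrr::pmap(protocol$phases, function(label, start, duration,
                                                   intensity, wavelength) {
      list(label = label, duration = duration, intensity = intensity,
           wavelength = if (is.na(wavelength)) NULL else wavelength)
    }),
    pulses = protocol$pulses
  )
  header <- "# illumination protocol: durations in seconds, intensities in umol photons m-2 s-1\n"
  writeLines(paste0(header, yaml::as.yaml(obj)), path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  obj <- yaml::read_yaml(path)
  phases <- purrr::map_dfr(obj$phases, function(ph) {
    tibble::tibble(
      label = ph$label, duration = ph$duration, intensity = ph$intensity,
      wavelength = if (is.null(ph$wavelength)) NA_real_ else ph$wavelength
    )
  })
  npq_protocol(
    phases,
    pulse_period = obj$pulses$period,
    pulse_duration = obj$pulses$duration,
    pulse_intensity = obj$pulses$intensity,
    pulse_wavelength = obj$pulses$wavelength
  )
}
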