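#' Kinetic parameters of an elementary NPQ component
#'
#' Phenomenological first-order kinetics for the three elementary
#' nonphotochemical-quenching components. Defaults reflect the canonical
#' time scales: energy-dependent quenching (qE) engages within seconds of
#' light onset, passes through a transitory maximum before partially
#' relaxing in the light, and relaxes within seconds in the dark; state
#' transitions (qT) develop and relax over minutes; photoinhibition (qI)
#' builds up slowly in the light and does not recover in the dark.
#'
#' @param component One of `"qE"`, `"qT"`, `"qI"`.
#' @param tau_rise Rise time constant in the light (s).
#' @param tau_relax Relaxation time constant in the opposite illumination
#'   state (s).
#' @param transitory_fraction qE only: fraction of the initial quenching
#'   retained after the in-light partial relaxation (in `[0, 1]`).
#' @param tau_transitory qE only: time constant of that in-light partial
#'   relaxation (s).
#' @param frozen_in_dark qI only: if `TRUE` the component does not relax in
#'   the dark.
#' @return A list of class `npq_kinetics`.
#' @export
component_kinetics <- function(component = c("qE", "qT", "qI"),
                               tau_rise = NULL,
                               tau_relax = NULL,
                               transitory_fraction = NULL,
                               tau_transitory = NULL,
                               frozen_in_dark = NULL) {
  component <- match.arg(component)
  defaults <- switch(component,
    qE = list(tau_rise = 30, tau_relax = 30, transitory_fraction = 0.6,
              tau_transitory = 300, frozen_in_dark = FALSE),
    qT = list(tau_rise = 200, tau_relax = 300, transitory_fraction = 1,
              tau_transitory = Inf, frozen_in_dark = FALSE),
    qI = list(tau_rise = 900, tau_relax = Inf, transitory_fraction = 1,
              tau_transitory = Inf, frozen_in_dark = TRUE)
  )
  k <- defaults
  for (nm in names(defaults)) {
    val <- get(nm)
    if (!is.null(val)) k[[nm]] <- val
  }
  if (k$tau_rise <= 0 || k$tau_relax <= 0 || k$tau_transitory <= 0) {
    stop("time constants must be positive", call. = FALSE)
  }
  if (k$transitory_fraction < 0 || k$transitory_fraction > 1) {
    stop("transitory_fraction must lie in [0, 1]", call. = FALSE)
  }
  k$component <- component
  structure(k, class = "npq_kinetics")
}

# Evaluate one component's dimensionless activation at arbitrary times.
# State is propagated phase by phase so each phase continues from the
# previous phase's end value. qE carries two states: the fast engagement r
# and the transitory modulation m (in-light relaxation toward
# transitory_fraction); the observed activation is r * m. On entering a
# dark phase m is folded into r so the dark decay is a single exponential
# with tau_relax.
component_activation <- function(times, protocol, component, kinetics) {
  ph <- protocol$phases
  out <- numeric(length(times))
  r <- 0    # engagement state in [0, 1]
  m <- 1    # qE transitory modulation state
  for (i in seq_len(nrow(ph))) {
    t0 <- ph$start[i]
    t1 <- t0 + ph$duration[i]
    lit <- ph$intensity[i] > 0
    last <- i == nrow(ph)
    sel <- times >= t0 & (if (last) times <= t1 else times < t1)
    s <- times[sel] - t0
    if (lit) {
      rs <- 1 - (1 - r) * exp(-s / kinetics$tau_rise)
      ms <- if (component == "qE") {
        kinetics$transitory_fraction +
          (m - kinetics$transitory_fraction) * exp(-s / kinetics$tau_transitory)
      } else rep(1, length(s))
      out[sel] <- rs * ms
      send <- t1 - t0
      r <- 1 - (1 - r) * exp(-send / kinetics$tau_rise)
      if (component == "qE") {
        m <- kinetics$transitory_fraction +
          (m - kinetics$transitory_fraction) * exp(-send / kinetics$tau_transitory)
      }
    } else {
      e0 <- r * m
      if (component == "qI" && kinetics$frozen_in_dark) {
        out[sel] <- e0
      } else {
        out[sel] <- e0 * exp(-s / kinetics$tau_relax)
        r <- e0 * exp(-(t1 - t0) / kinetics$tau_relax)
        m <- 1
      }
      if (component == "qI" && kinetics$frozen_in_dark) {
        r <- e0
        m <- 1
      }
    }
  }
  out
}

#' Elementary component basis sampled at the pulse times
#'
#' Evaluates the dimensionless activation (in `[0, 1]`) of one elementary
#' NPQ component under a protocol, sampled at the saturating-pulse times.
#'
#' @param protocol An [npq_protocol()].
#' @param component One of `"qE"`, `"qT"`, `"qI"`.
#' @param kinetics An [component_kinetics()] object; defaults to the
#'   component's standard kinetics.
#' @return Numeric vector of length `length(pulse_times(protocol))`.
#' @export
#' @examples
#' b <- component_basis(reference_protocol(), "qT")
#' b[1]  # 0: no state transitions before light onset
component_basis <- function(protocol, component = c("qE", "qT", "qI"),
                            kinetics = component_kinetics(component)) {
  component <- match.arg(component)
  stopifnot(inherits(protocol, "npq_protocol"))
  component_activation(pulse_times(protocol), protocol, component, kinetics)
}

#' All three component bases for a protocol
#'
#' @inheritParams component_basis
#' @param kinetics_list Named list with elements `qE`, `qT`, `qI` of
#'   [component_kinetics()] objects.
#' @return Named list of three basis vectors (`qE`, `qT`, `qI`).
#' @export
component_bases <- function(protocol,
                            kinetics_list = list(qE = component_kinetics("qE"),
                                                 qT = component_kinetics("qT"),
                                                 qI = component_kinetics("qI"))) {
  purrr::imap(kinetics_list, function(k, nm) component_basis(protocol, nm, k))
}

#' Parameters of one simulated cell
#'
#' @param F0 Baseline maximal fluorescence (arbitrary units, > 0).
#' @param A_qE,A_qT,A_qI Dimensionless component amplitudes (>= 0).
#' @param noise_sigma Relative (multiplicative) measurement noise SD.
#' @return A list of class `npq_cell_params`.
#' @export
cell_params <- function(F0 = 1000, A_qE = 0, A_qT = 0, A_qI = 0,
                        noise_sigma = 0) {
  stopifnot(F0 > 0, A_qE >= 0, A_qT >= 0, A_qI >= 0, noise_sigma >= 0)
  structure(list(F0 = F0, A_qE = A_qE, A_qT = A_qT, A_qI = A_qI,
                 noise_sigma = noise_sigma),
            class = "npq_cell_params")
}

#' Simulate one Fm' trace
#'
#' The quenched maximal fluorescence at pulse time `t_k` is
#' `F(t_k) = F0 * (1 - A_qE * e(t_k) + A_qT * g(t_k) - A_qI * h(t_k)) * (1 + eps_k)`
#' with `e`, `g`, `h` the qE/qT/qI component bases (qT raises Fm' because
#' antenna migration to PSII increases its cross-section) and `eps_k`
#' i.i.d. `Normal(0, noise_sigma^2)` multiplicative noise.
#'
#' @param params A [cell_params()] object.
#' @param protocol An [npq_protocol()].
#' @param bases Named list of bases as from [component_bases()].
#' @param seed Optional integer seed for the noise draw; when `NULL` the
#'   current RNG stream is used.
#' @return Numeric Fm' vector, one value per pulse, all positive.
#' @export
simulate_trace <- function(params, protocol,
                           bases = component_bases(protocol),
                           seed = NULL) {
  stopifnot(inherits(params, "npq_cell_params"))
  quench <- params$A_qE * max(bases$qE) + params$A_qI * max(bases$qI)
  if (quench >= 1) {
    stop("amplitudes too large: A_qE*max(e) + A_qI*max(h) = ",
         signif(quench, 4), " >= 1 would drive Fm' non-positive",
         call. = FALSE)
  }
  clean <- params$F0 *
    (1 - params$A_qE * bases$qE + params$A_qT * bases$qT - params$A_qI * bases$qI)
  if (params$noise_sigma == 0) return(clean)
  draw <- function() stats::rnorm(length(clean), 0, params$noise_sigma)
  eps <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  clean * (1 + eps)
}

#' Specification of a simulated cell population
#'
#' Per-cell component amplitudes are drawn log-normally (median and
#' coefficient of variation per component), giving positive-support
#' cell-to-cell dispersion. Label presets mirror the four reference
#' populations of the training design — a quenching-null population
#' (`pop_0`), single-component qE, qT and qI populations — plus a
#' wild-type-like mixture expressing qE and qT together. Preset cell
#' counts for the four reference populations are the reference dataset
#' sizes (433, 480, 936, 453; total 2302 with `pop_0`).
#'
#' @param label One of `"pop_0"`, `"pop_qe"`, `"pop_qt"`, `"pop_qi"`, `"wt"`.
#' @param n_cells Number of cells (`NULL` = label preset).
#' @param amplitude_median Named numeric `(qE, qT, qI)` of median amplitudes
#'   (`NULL` = label preset).
#' @param amplitude_cv Named numeric `(qE, qT, qI)` of log-normal CVs.
#' @param noise_sigma Relative multiplicative measurement noise SD.
#' @param F0_median,F0_cv Log-normal baseline fluorescence parameters.
#' @param seed Integer RNG seed; every draw of the population is a pure
#'   function of the spec (including this seed) and the protocol.
#' @return A list of class `npq_population_spec`.
#' @export
population_spec <- function(label = c("pop_0", "pop_qe", "pop_qt", "pop_qi", "wt"),
                            n_cells = NULL,
                            amplitude_median = NULL,
                            amplitude_cv = NULL,
                            noise_sigma = 0.02,
                            F0_median = 1000, F0_cv = 0.3,
                            seed = 1L) {
  label <- match.arg(label)
  preset <- switch(label,
    pop_0  = list(n = 433, med = c(qE = 0,   qT = 0,   qI = 0)),
    pop_qe = list(n = 480, med = c(qE = 0.6, qT = 0,   qI = 0)),
    pop_qt = list(n = 936, med = c(qE = 0,   qT = 0.3, qI = 0)),
    pop_qi = list(n = 453, med = c(qE = 0,   qT = 0,   qI = 0.35)),
    wt     = list(n = 300, med = c(qE = 0.6, qT = 0.3, qI = 0))
  )
  if (is.null(n_cells)) n_cells <- preset$n
  if (is.null(amplitude_median)) amplitude_median <- preset$med
  if (is.null(amplitude_cv)) amplitude_cv <- c(qE = 0.35, qT = 0.20, qI = 0.30)
  stopifnot(n_cells >= 1, all(amplitude_median >= 0), all(amplitude_cv >= 0))
  structure(
    list(label = label, n_cells = as.integer(n_cells),
         amplitude_median = amplitude_median[c("qE", "qT", "qI")],
         amplitude_cv = amplitude_cv[c("qE", "qT", "qI")],
         noise_sigma = noise_sigma,
         F0_median = F0_median, F0_cv = F0_cv, seed = as.integer(seed)),
    class = "npq_population_spec"
  )
}

#' The four reference population specs
#'
#' Convenience constructor for the training design: the quenching-null,
#' qE-only, qT-only and qI-only populations at their reference sizes,
#' with per-population seeds derived from a master seed.
#'
#' @param seed Master integer seed.
#' @param n_cells Optional common cell count overriding the presets.
#' @param noise_sigma Measurement noise SD passed to every spec.
#' @return Named list of four [population_spec()] objects
#'   (`pop_0`, `pop_qe`, `pop_qt`, `pop_qi`).
#' @export
reference_population_specs <- function(seed = 1L, n_cells = NULL,
                                       noise_sigma = 0.02) {
  labels <- c("pop_0", "pop_qe", "pop_qt", "pop_qi")
  specs <- purrr::imap(stats::setNames(seq_along(labels), labels), function(i, lab) {
    population_spec(lab, n_cells = n_cells, noise_sigma = noise_sigma,
                    seed = seed * 131L + i)
  })
  specs
}

# log-normal with given median and CV: meanlog = log(median),
# sdlog = sqrt(log(1 + cv^2)); the distribution's CV is then exactly cv.
rlnorm_median_cv <- function(n, median, cv) {
  if (median == 0) return(rep(0, n))
  if (cv == 0) return(rep(median, n))
  stats::rlnorm(n, meanlog = log(median), sdlog = sqrt(log(1 + cv^2)))
}

# Draw per-cell ground-truth parameters; amplitude combinations that would
# push Fm' to zero (quenching >= 0.95 of baseline) are rejection-resampled.
draw_cell_params <- function(spec, bases, max_quench = 0.95) {
  n <- spec$n_cells
  med <- spec$amplitude_median
  cv <- spec$amplitude_cv
  A_qE <- rlnorm_median_cv(n, med[["qE"]], cv[["qE"]])
  A_qT <- rlnorm_median_cv(n, med[["qT"]], cv[["qT"]])
  A_qI <- rlnorm_median_cv(n, med[["qI"]], cv[["qI"]])
  F0 <- rlnorm_median_cv(n, spec$F0_median, spec$F0_cv)
  quench <- A_qE * max(bases$qE) + A_qI * max(bases$qI)
  bad <- which(quench >= max_quench)
  guard <- 0
  while (length(bad) > 0 && guard < 1000) {
    A_qE[bad] <- rlnorm_median_cv(length(bad), med[["qE"]], cv[["qE"]])
    A_qI[bad] <- rlnorm_median_cv(length(bad), med[["qI"]], cv[["qI"]])
    quench <- A_qE * max(bases$qE) + A_qI * max(bases$qI)
    bad <- which(quench >= max_quench)
    guard <- guard + 1
  }
  if (length(bad) > 0) stop("could not draw admissible amplitudes", call. = FALSE)
  tibble::tibble(F0 = F0, A_qE = A_qE, A_qT = A_qT, A_qI = A_qI)
}

new_trace_set <- function(traces, ground_truth, ptimes, label, seed, rep_index = 1L) {
  structure(
    list(traces = traces, ground_truth = ground_truth, pulse_times = ptimes,
         label = label, seed = seed, repeat_index = rep_index),
    class = "npq_trace_set"
  )
}

#' Simulate a labelled cell population
#'
#' Draws per-cell ground-truth amplitudes and baselines from the spec's
#' log-normal dispersions and renders one noisy Fm' trace per cell. The
#' output is a pure function of `(spec, protocol)` — the spec carries the
#' seed.
#'
#' @param spec A [population_spec()].
#' @param protocol An [npq_protocol()].
#' @param kinetics_list Optional kinetics overrides, see [component_bases()].
#' @return An `npq_trace_set`: list with `traces` (long tibble with columns
#'   `cell_id`, `population`, `repeat`, `pulse_index`, `time_s`,
#'   `fm_value`), `ground_truth` (tibble of per-cell `F0`, `A_qE`, `A_qT`,
#'   `A_qI`), `pulse_times`, `label`, `seed`.
#' @export
#' @examples
#' ts <- simulate_population(population_spec("pop_qt", n_cells = 5), reference_protocol())
#' dplyr::count(ts$traces, cell_id)
simulate_population <- function(spec, protocol,
                                kinetics_list = NULL) {
  stopifnot(inherits(spec, "npq_population_spec"),
            inherits(protocol, "npq_protocol"))
  bases <- if (is.null(kinetics_list)) component_bases(protocol)
           else component_bases(protocol, kinetics_list)
  ptimes <- pulse_times(protocol)
  withr::with_seed(spec$seed, {
    gt <- draw_cell_params(spec, bases)
    mat <- simulate_trace_matrix(gt, bases, spec$noise_sigma)
  })
  gt$cell_id <- sprintf("%s_%04d", spec$label, seq_len(spec$n_cells))
  gt <- dplyr::relocate(gt, "cell_id")
  traces <- trace_matrix_to_long(mat, gt$cell_id, spec$label, ptimes, 1L)
  new_trace_set(traces, gt, ptimes, spec$label, spec$seed)
}

# vectorized rendering: rows = cells, cols = pulses; uses the current RNG
simulate_trace_matrix <- function(gt, bases, noise_sigma) {
  n <- nrow(gt)
  Tn <- length(bases$qE)
  clean <- gt$F0 *
    (1 - outer(gt$A_qE, bases$qE) + outer(gt$A_qT, bases$qT) -
       outer(gt$A_qI, bases$qI))
  if (noise_sigma > 0) {
    clean <- clean * (1 + matrix(stats::rnorm(n * Tn, 0, noise_sigma), n, Tn))
  }
  clean
}

trace_matrix_to_long <- function(mat, cell_ids, label, ptimes, rep_index) {
  tibble::tibble(
    cell_id = rep(cell_ids, each = length(ptimes)),
    population = label,
    `repeat` = rep_index,
    pulse_index = rep(seq_along(ptimes), times = length(cell_ids)),
    time_s = rep(ptimes, times = length(cell_ids)),
    fm_value = as.vector(t(mat))
  )
}

#' Extract the cell-by-pulse trace matrix from a trace set or long tibble
#'
#' @param x An `npq_trace_set` or a long tibble with columns `cell_id`,
#'   `pulse_index`, `fm_value`.
#' @return Numeric matrix, rows = cells (named by `cell_id`, in order of
#'   first appearance), columns = pulses.
#' @export
trace_matrix <- function(x) {
  df <- if (inherits(x, "npq_trace_set")) x$traces else tibble::as_tibble(x)
  ids <- unique(df$cell_id)
  Tn <- max(df$pulse_index)
  m <- matrix(NA_real_, length(ids), Tn, dimnames = list(ids, NULL))
  m[cbind(match(df$cell_id, ids), df$pulse_index)] <- df$fm_value
  if (anyNA(m)) stop("incomplete traces: every cell needs every pulse", call. = FALSE)
  m
}

#' @export
print.npq_trace_set <- function(x, ...) {
  cat("<npq_trace_set>", x$label, "-", nrow(x$ground_truth), "cells x",
      length(x$pulse_times), "pulses (seed", x$seed, ")\n")
  invisible(x)
}

#' @export
as_tibble.npq_trace_set <- function(x, ...) x$traces

#' Simulate two consecutive repeats of the same experiment
#'
#' Both repeats share identical per-cell ground-truth amplitudes and differ
#' only in the measurement-noise realization; cell order is aligned, so row
#' `i` of either repeat is the same cell. This emulates re-running the
#' light protocol on the same immobilized cells.
#'
#' @inheritParams simulate_population
#' @return List of two `npq_trace_set`s (`repeat_index` 1 and 2).
#' @export
simulate_repeat_pair <- function(spec, protocol, kinetics_list = NULL) {
  stopifnot(inherits(spec, "npq_population_spec"))
  bases <- if (is.null(kinetics_list)) component_bases(protocol)
           else component_bases(protocol, kinetics_list)
  ptimes <- pulse_times(protocol)
  withr::with_seed(spec$seed, {
    gt <- draw_cell_params(spec, bases)
    mat1 <- simulate_trace_matrix(gt, bases, spec$noise_sigma)
    mat2 <- simulate_trace_matrix(gt, bases, spec$noise_sigma)
  })
  gt$cell_id <- sprintf("%s_%04d", spec$label, seq_len(spec$n_cells))
  gt <- dplyr::relocate(gt, "cell_id")
  list(
    new_trace_set(trace_matrix_to_long(mat1, gt$cell_id, spec$label, ptimes, 1L),
                  gt, ptimes, spec$label, spec$seed, 1L),
    new_trace_set(trace_matrix_to_long(mat2, gt$cell_id, spec$label, ptimes, 2L),
                  gt, ptimes, spec$label, spec$seed, 2L)
  )
}

#' Render a synthetic fluorescence movie with ground truth
#'
#' Places non-overlapping disk-shaped cells at rejection-sampled positions
#' and renders one frame per saturating pulse: background level plus, inside
#' each disk, an intensity proportional to that cell's Fm' value at the
#' pulse, optionally degraded by Poisson shot noise. The ground-truth label
#' mask and trace set are returned alongside.
#'
#' @inheritParams simulate_population
#' @param height,width Frame size in pixels.
#' @param cell_radius_px Disk radius in pixels.
#' @param background Constant background intensity (a.u.).
#' @param gain Conversion from Fm' units to pixel intensity.
#' @param shot_noise If `TRUE`, each pixel value `v` is replaced by a
#'   Poisson draw with mean `v` (counts), emulating shot noise.
#' @return List with `frames` (array `height x width x n_pulses`),
#'   `timestamps` (= pulse times), `mask` (integer `height x width`
#'   ground-truth label image, 0 = background), `trace_set`
#'   (the planted `npq_trace_set`) and `protocol`.
#' @export
simulate_movie <- function(spec, protocol, height = 512, width = 512,
                           cell_radius_px = 6, background = 20,
                           gain = 0.1, shot_noise = FALSE,
                           kinetics_list = NULL) {
  ts <- simulate_population(spec, protocol, kinetics_list)
  mat <- trace_matrix(ts)
  n <- nrow(mat)
  r <- cell_radius_px
  centers <- withr::with_seed(spec$seed + 7919L, {
    place_disks(n, height, width, r, min_sep = 2 * r + 3, margin = r + 2)
  })
  mask <- matrix(0L, height, width)
  pix <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- pmax(1, centers[i, 1] - r):pmin(height, centers[i, 1] + r)
    cols <- pmax(1, centers[i, 2] - r):pmin(width, centers[i, 2] + r)
    grid <- expand.grid(row = rows, col = cols)
    keep <- (grid$row - centers[i, 1])^2 + (grid$col - centers[i, 2])^2 <= r^2
    idx <- as.matrix(grid[keep, ])
    mask[idx] <- i
    pix[[i]] <- (idx[, 2] - 1L) * height + idx[, 1]   # linear indices
  }
  Tn <- ncol(mat)
  frames <- array(background, dim = c(height, width, Tn))
  for (k in seq_len(Tn)) {
    fr <- frames[, , k]
    for (i in seq_len(n)) fr[pix[[i]]] <- background + gain * mat[i, k]
    frames[, , k] <- fr
  }
  if (shot_noise) {
    frames <- withr::with_seed(spec$seed + 104729L, {
      array(stats::rpois(length(frames), frames), dim = dim(frames))
    })
  }
  list(frames = frames, timestamps = pulse_times(protocol), mask = mask,
       trace_set = ts, protocol = protocol)
}

# rejection-sample n disk centers with pairwise separation >= min_sep
place_disks <- function(n, height, width, radius, min_sep, margin,
                        max_attempts = 20000L * n) {
  centers <- matrix(0L, n, 2)
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("cannot place ", n, " non-overlapping cells of radius ", radius,
           " in ", height, "x", width, call. = FALSE)
    }
    cand <- c(sample(seq(margin + 1L, height - margin), 1),
              sample(seq(margin + 1L, width - margin), 1))
    if (placed > 0L) {
      d2 <- (centers[seq_len(placed), 1] - cand[1])^2 +
            (centers[seq_len(placed), 2] - cand[2])^2
      if (any(d2 < min_sep^2)) next
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }
  centers
}
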