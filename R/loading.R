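#' Transvalvular pressure waveform
#'
#' A sampled pressure-difference waveform over one cardiac cycle,
#' interpolated piecewise-linearly. Positive values act
#' ventricular-to-atrial, i.e. close the valve. Time zero is end
#' diastole (valve open, near-zero gradient).
#'
#' @param samples data frame with columns `t` (ms) and `dP` (kPa) covering
#'   `[0, cycle]`; if `NULL` the default physiologic shape is built from
#'   the peak values.
#' @param peak_systolic maximum systolic gradient (kPa), default 15.4.
#' @param peak_diastolic minimum (diastolic) gradient (kPa), default -2.9.
#' @param cycle cycle duration (ms), default 800.
#' @param t_peak time of peak systole (ms), default 250.
#' @return object of class `pressure_waveform` with elements `samples`
#'   (tibble), `peak_systolic`, `peak_diastolic`, `cycle`, `t_peak`.
#' @details The default shape rises smoothly (half-cosine) from 0 at end
#'   diastole to the systolic peak, falls to the diastolic trough at 75%
#'   of the cycle, and recovers to 0 at the cycle end. The printed extrema
#'   are exact samples; everything between them is a modeling choice that
#'   users replace with their own two-column table when gated data exist.
#' @export
pressure_waveform <- function(samples = NULL, peak_systolic = 15.4,
                              peak_diastolic = -2.9, cycle = 800,
                              t_peak = 250) {
  if (is.null(samples)) {
    t_trough <- 0.75 * cycle
    up   <- seq(0, t_peak, length.out = 26)
    down <- seq(t_peak, t_trough, length.out = 26)[-1]
    tail <- seq(t_trough, cycle, length.out = 9)[-1]
    dP <- c(peak_systolic * (1 - cos(pi * up / t_peak)) / 2,
            peak_diastolic + (peak_systolic - peak_diastolic) *
              (1 + cos(pi * (down - t_peak) / (t_trough - t_peak))) / 2,
            peak_diastolic * (1 + cos(pi * (tail - t_trough) /
                                        (cycle - t_trough))) / 2)
    samples <- data.frame(t = c(up, down, tail), dP = dP)
  }
  samples <- as.data.frame(samples)
  if (!all(c("t", "dP") %in% names(samples)) || nrow(samples) < 1L)
    stop("pressure_waveform: samples need columns t, dP and >= 1 row",
         call. = FALSE)
  samples <- samples[order(samples$t), , drop = FALSE]
  structure(list(samples = tibble::as_tibble(samples),
                 peak_systolic = max(samples$dP),
                 peak_diastolic = min(samples$dP),
                 cycle = max(samples$t),
                 t_peak = samples$t[which.max(samples$dP)]),
            class = "pressure_waveform")
}

#' Evaluate the pressure waveform
#'
#' Piecewise-linear interpolation of the sampled waveform; times outside
#' one cycle wrap modulo the cycle duration.
#'
#' @param t time(s) in ms (vectorized).
#' @param waveform a [pressure_waveform()].
#' @return pressure gradient(s) in kPa.
#' @export
pressure_at <- function(t, waveform) {
  stopifnot(inherits(waveform, "pressure_waveform"))
  s <- waveform$samples
  if (nrow(s) == 0L) stop("pressure_at: empty waveform", call. = FALSE)
  if (nrow(s) == 1L) return(rep(s$dP, length(t)))
  tm <- t %% waveform$cycle
  stats::approx(s$t, s$dP, xout = tm, rule = 2)$y
}

#' Prescribed annular motion between two gated configurations
#'
#' Annular node positions are interpolated between the peak-systolic and
#' end-diastolic configurations along fixed per-node direction vectors
#' `d_i = x_i(diastole) - x_i(systole)`:
#' `x_i(t) = x_i(systole) + g(t) d_i`, with a dimensionless gating signal
#' `g(t)` in `[0, 1]` (`g = 0` at peak systole, `g = 1` at end diastole).
#'
#' @param config_systole,config_diastole matrices `n x 3` (mm) with
#'   identical node ordering.
#' @param gating data frame with columns `t` (ms) and `g` in `[0,1]`; if
#'   `NULL`, a default synchronized with [pressure_waveform()] is built
#'   (g = 1 at t = 0 end diastole, 0 at `t_peak`, back to 1 at cycle end).
#' @param cycle,t_peak cycle duration and peak-systole time (ms), used
#'   only for the default gating.
#' @return object of class `annular_motion`.
#' @export
annular_motion <- function(config_systole, config_diastole, gating = NULL,
                           cycle = 800, t_peak = 250) {
  config_systole <- as.matrix(config_systole)
  config_diastole <- as.matrix(config_diastole)
  if (!identical(dim(config_systole), dim(config_diastole)))
    stop("annular_motion: configurations must have matched node counts",
         call. = FALSE)
  stopifnot(ncol(config_systole) == 3L)
  if (is.null(gating)) {
    t1 <- seq(0, t_peak, length.out = 21)
    t2 <- seq(t_peak, cycle, length.out = 21)[-1]
    gating <- data.frame(
      t = c(t1, t2),
      g = c((1 + cos(pi * t1 / t_peak)) / 2,
            (1 - cos(pi * (t2 - t_peak) / (cycle - t_peak))) / 2))
  }
  gating <- as.data.frame(gating)
  stopifnot(all(c("t", "g") %in% names(gating)),
            all(gating$g >= -1e-12), all(gating$g <= 1 + 1e-12))
  structure(list(config_systole = config_systole,
                 config_diastole = config_diastole,
                 direction = config_diastole - config_systole,
                 gating = tibble::as_tibble(gating),
                 cycle = max(gating$t)),
            class = "annular_motion")
}

gating_at <- function(t, motion) {
  g <- motion$gating
  stats::approx(g$t, g$g, xout = t %% motion$cycle, rule = 2)$y
}

#' Annular node positions at a time point
#'
#' @param t time in ms.
#' @param motion an [annular_motion()].
#' @return `n x 3` matrix of annular node coordinates (mm). Exactly the
#'   systolic configuration where the gating is 0 and the diastolic one
#'   where it is 1.
#' @export
annulus_position <- function(t, motion) {
  stopifnot(inherits(motion, "annular_motion"))
  g <- gating_at(t, motion)
  motion$config_systole + g * motion$direction
}

#' Build an annular motion program from a valve mesh
#'
#' The mesh's annulus (its end-diastolic, open configuration) is taken as
#' `config_diastole`; `config_systole` is built by scaling the annulus
#' about its centroid so the intercommissural distance matches
#' `alpm_systole` (the paper-style gated measurement pair: 37 mm at end
#' diastole, 35 mm at peak systole).
#'
#' @param mesh a [valve_mesh()] in its end-diastolic configuration.
#' @param alpm_systole target intercommissural distance at peak systole
#'   (mm).
#' @param cycle,t_peak cycle duration and peak-systole time (ms) for the
#'   default gating.
#' @return an [annular_motion()] whose node order matches
#'   `mesh$annulus_ids`.
#' @export
annular_motion_from_mesh <- function(mesh, alpm_systole = 35,
                                     cycle = 800, t_peak = 250) {
  dia <- mesh$nodes[mesh$annulus_ids, , drop = FALSE]
  d <- measure_annulus(mesh)
  s <- alpm_systole / d[["alpm_diameter_mm"]]
  ctr <- colMeans(dia)
  sys <- sweep(sweep(dia, 2, ctr) * s, 2, ctr, "+")
  annular_motion(config_systole = sys, config_diastole = dia,
                 cycle = cycle, t_peak = t_peak)
}

#' Read a two-column time-series CSV (time_ms, value)
#'
#' Shared reader for user-supplied pressure waveforms and gating signals.
#'
#' @param path CSV path; first column time (ms), second column value.
#' @return a two-column data frame named `t`, `value`.
#' @export
read_timeseries_csv <- function(path) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2L) stop("read_timeseries_csv: need two columns", call. = FALSE)
  stats::setNames(d[, 1:2], c("t", "value"))
}
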