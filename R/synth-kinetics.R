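#' Exponential aggregation kinetics model
#'
#' Phenomenological model of the normalized projected-area curve during
#' anchorage-independent aggregation:
#' `A(t) = a_inf + (1 - a_inf) * exp(-k * max(0, t - lag))`.
#' `A(0) = 1` by construction and the curve decays monotonically to the
#' plateau `a_inf`. The functional form is configuration for the synthetic
#' generator, not a mechanistic claim.
#'
#' @param a_inf plateau of the normalized area, in `(0, 1]`.
#' @param k aggregation rate (per hour), non-negative.
#' @param lag delay (hours) before compaction starts, non-negative.
#' @return A `kinetics_model` object.
#' @export
kinetics_model <- function(a_inf, k, lag = 0) {
  if (!is.numeric(a_inf) || length(a_inf) != 1 || a_inf <= 0 || a_inf > 1)
    stop("'a_inf' must be a single value in (0, 1]")
  if (k < 0) stop("'k' must be non-negative")
  if (lag < 0) stop("'lag' must be non-negative")
  structure(list(a_inf = a_inf, k = k, lag = lag), class = "kinetics_model")
}

#' Evaluate a kinetics model at given times
#'
#' @param model a [kinetics_model()].
#' @param t_h times in hours.
#' @return Normalized area values.
#' @export
kinetics_area <- function(model, t_h) {
  stopifnot(inherits(model, "kinetics_model"))
  model$a_inf + (1 - model$a_inf) * exp(-model$k * pmax(0, t_h - model$lag))
}

#' Closed-form area under the kinetics model curve
#'
#' Integral of `A(t)` over `[0, window_h]`, used as the analytic oracle for
#' the trapezoidal AUC of sampled curves.
#'
#' @param model a [kinetics_model()].
#' @param window_h integration window (hours).
#' @return AUC in hours.
#' @export
kinetics_auc <- function(model, window_h) {
  stopifnot(inherits(model, "kinetics_model"), window_h > 0)
  a <- model$a_inf; k <- model$k; lag <- min(model$lag, window_h)
  tail_h <- window_h - lag
  if (k == 0) return(lag + a * tail_h + (1 - a) * tail_h)
  lag * 1 + a * tail_h + (1 - a) * (1 - exp(-k * tail_h)) / k
}

#' Acquisition geometry of the time-lapse assay
#'
#' Defaults mirror a 10x bright-field time-lapse acquisition: 0.645 um/px,
#' z-stacks of 20-um spaced planes spanning 160 um (hence
#' `floor(160/20) + 1 = 9` planes), one frame every 15 min.
#'
#' @param pixel_size um per pixel.
#' @param plane_spacing z spacing between focal planes (um).
#' @param depth_span total z range covered by the stack (um).
#' @param frame_interval hours between frames.
#' @param duration total movie duration (hours).
#' @param image_shape `c(rows, cols)` in pixels.
#' @return An `acquisition_geometry` object with computed `n_planes`.
#' @export
acquisition_geometry <- function(pixel_size = 0.645, plane_spacing = 20,
                                 depth_span = 160, frame_interval = 0.25,
                                 duration = 6, image_shape = c(512L, 512L)) {
  if (duration <= 0) stop("'duration' must be positive")
  if (plane_spacing <= 0 || depth_span < 0) stop("invalid z geometry")
  if (length(image_shape) == 1L) image_shape <- rep(image_shape, 2L)
  structure(list(pixel_size = pixel_size, plane_spacing = plane_spacing,
                 depth_span = depth_span,
                 n_planes = as.integer(floor(depth_span / plane_spacing)) + 1L,
                 frame_interval = frame_interval, duration = duration,
                 image_shape = as.integer(image_shape)),
            class = "acquisition_geometry")
}

#' Sample a kinetics model on the acquisition time grid
#'
#' @param model a [kinetics_model()].
#' @param geometry an [acquisition_geometry()].
#' @return Data frame with `time_h` and `normalized_area`, sampled every
#'   `frame_interval` from 0 to `duration`; first value is exactly 1 and the
#'   series is non-increasing with all values `>= a_inf`.
#' @export
simulate_kinetics <- function(model, geometry = acquisition_geometry()) {
  stopifnot(inherits(model, "kinetics_model"),
            inherits(geometry, "acquisition_geometry"))
  t_h <- seq(0, geometry$duration, by = geometry$frame_interval)
  data.frame(time_h = t_h, normalized_area = kinetics_area(model, t_h))
}

#' Simulate replicate aggregation curves for one condition
#'
#' Draws per-replicate kinetics models around a condition mean (plateau
#' jittered additively, rate multiplicatively) and adds multiplicative
#' measurement noise to the sampled normalized areas, re-normalizing so the
#' first frame is exactly 1. Default dispersions are chosen to reproduce
#' the replicate coefficient of variation (about 5-10% on AUC) typical of
#' this assay.
#'
#' @param model condition-mean [kinetics_model()].
#' @param geometry an [acquisition_geometry()].
#' @param n_replicates number of wells.
#' @param ainf_sd additive between-replicate sd of the plateau.
#' @param k_rel_sd multiplicative (lognormal) sd of the rate.
#' @param area_noise_sd multiplicative per-frame measurement noise sd.
#' @param seed RNG seed.
#' @return List of [build_curve()] `aggregation_curve` objects.
#' @export
simulate_condition <- function(model, geometry = acquisition_geometry(),
                               n_replicates = 30, ainf_sd = 0.03,
                               k_rel_sd = 0.1, area_noise_sd = 0.02,
                               seed = 1) {
  stopifnot(inherits(model, "kinetics_model"))
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(i) {
      a <- min(1, max(1e-3, model$a_inf + rnorm(1, 0, ainf_sd)))
      k <- model$k * exp(rnorm(1, 0, k_rel_sd))
      m <- kinetics_model(a, k, model$lag)
      y <- simulate_kinetics(m, geometry)$normalized_area
      y <- y * exp(rnorm(length(y), 0, area_noise_sd))
      y <- y / y[1]
      build_curve(y * 1000, frame_interval_h = geometry$frame_interval,
                  well_id = sprintf("rep_%02d", i))
    })
  })
}
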