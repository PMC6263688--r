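#' Rectangular region of interest
#'
#' Pixel coordinates are 0-based with x = column and y = row, origin at the
#' top-left pixel center; the rectangle is half-open, `[x0, x1) x [y0, y1)`.
#'
#' @param x0,y0,x1,y1 integer pixel bounds.
#' @return An object of class `rect_roi`.
#' @export
rect_roi <- function(x0, y0, x1, y1) {
  v <- as.integer(c(x0, y0, x1, y1))
  if (anyNA(v)) stop("ROI bounds must be integers")
  if (!(v[1] < v[3] && v[2] < v[4])) stop("ROI must satisfy x0 < x1 and y0 < y1")
  if ((v[3] - v[1]) * (v[4] - v[2]) < 16L) stop("ROI area must be at least 16 px")
  structure(list(x0 = v[1], y0 = v[2], x1 = v[3], y1 = v[4]), class = "rect_roi")
}

#' @export
print.rect_roi <- function(x, ...) {
  cat(sprintf("<rect_roi> [%d,%d) x [%d,%d)  (%d x %d px)\n",
              x$x0, x$x1, x$y0, x$y1, x$x1 - x$x0, x$y1 - x$y0))
  invisible(x)
}

check_roi <- function(roi, frame_dim) {
  stopifnot(inherits(roi, "rect_roi"))
  if (roi$x1 > frame_dim[2] || roi$y1 > frame_dim[1])
    stop("ROI exceeds frame bounds (", frame_dim[2], " x ", frame_dim[1], " px)")
  invisible(roi)
}

#' Species breathing passbands
#'
#' Anesthesia lowers breathing rates well below the awake norms, so the
#' filter bands reach below them: mice 1-4.6 Hz (60-276 breaths/min with
#' harmonics), rats 0.6-3.3 Hz. The upper cutoff deliberately includes the
#' first harmonic of plausible rates, which sharpens spectral peak picking.
#'
#' @param species `"rat"` or `"mouse"`.
#' @return `c(low, high)` in Hz.
#' @export
species_passband <- function(species = c("rat", "mouse")) {
  switch(match.arg(species), rat = c(0.6, 3.3), mouse = c(1, 4.6))
}

#' Pipeline configuration
#'
#' Collects every tunable of the respiratory-rate and tracking pipelines with
#' the defaults used throughout the package. Pass `species = "custom"`
#' together with an explicit `passband_hz` for other animals.
#'
#' @param species `"rat"`, `"mouse"` or `"custom"`.
#' @param passband_hz breathing band `c(low, high)` in Hz; defaults to the
#'   species preset.
#' @param rr_window_s spectral analysis window length in seconds.
#' @param rr_hop_s hop between successive windows in seconds.
#' @param median_s trailing-median length for the smoothed rate, seconds.
#' @param n_features number of Shi-Tomasi points detected in the first frame.
#' @param prune_percentile percentage of the most displaced trajectories
#'   discarded before source separation.
#' @param n_pcs number of principal components retained.
#' @param harmonic_halfwidth_hz half-width of the spectral bands around the
#'   dominant frequency and its first harmonic in the periodicity score.
#' @param stretch_lo_pct,stretch_hi_pct contrast-stretch clipping percentiles.
#' @param otsu_classes number of Otsu intensity classes (foreground = warmest).
#' @param min_feature_distance minimum mutual distance between feature
#'   points, px.
#' @param tracker list of particle-filter settings, see Details.
#' @param heatmap list with `grid_n` (occupancy grid size) and `center_frac`
#'   (linear fraction of the arena forming the center zone).
#' @param rng_seed seed used by stochastic stages (particle tracker).
#'
#' @details `tracker` fields: `n_particles` (300), `patch` (16x16),
#' `n_templates` (10), `lambda` (0.01, l1 weight), `alpha` (50, error to
#' particle-weight scale), `tau` (0.7, template-update similarity threshold),
#' `sigma_xy` (1.5 px transition noise), `sigma_scale` (0.01 log-scale noise).
#'
#' @return An object of class `run_config`.
#' @export
run_config <- function(species = c("rat", "mouse", "custom"),
                       passband_hz = NULL,
                       rr_window_s = 10, rr_hop_s = 1, median_s = 5,
                       n_features = 100, prune_percentile = 25, n_pcs = 6,
                       harmonic_halfwidth_hz = 0.05,
                       stretch_lo_pct = 1, stretch_hi_pct = 99,
                       otsu_classes = 3, min_feature_distance = 2,
                       tracker = list(), heatmap = list(), rng_seed = 1L) {
  species <- match.arg(species)
  if (is.null(passband_hz)) {
    if (species == "custom") stop("`passband_hz` is required for species = \"custom\"")
    passband_hz <- species_passband(species)
  }
  if (length(passband_hz) != 2L || !(0 < passband_hz[1] && passband_hz[1] < passband_hz[2]))
    stop("`passband_hz` must satisfy 0 < low < high")
  trk <- utils::modifyList(list(n_particles = 300L, patch = c(16L, 16L),
                                n_templates = 10L, lambda = 0.01, alpha = 50,
                                tau = 0.7, sigma_xy = 1.5, sigma_scale = 0.01,
                                tol = 1e-5, maxit = 20L), tracker)
  hm <- utils::modifyList(list(grid_n = 32L, center_frac = 0.5,
                               immobility_speed = 5, immobility_min_s = 1,
                               velocity_smooth_s = 0.5), heatmap)
  structure(list(species = species, passband_hz = passband_hz,
                 rr_window_s = rr_window_s, rr_hop_s = rr_hop_s,
                 median_s = median_s, n_features = n_features,
                 prune_percentile = prune_percentile, n_pcs = n_pcs,
                 harmonic_halfwidth_hz = harmonic_halfwidth_hz,
                 stretch_lo_pct = stretch_lo_pct, stretch_hi_pct = stretch_hi_pct,
                 otsu_classes = otsu_classes,
                 min_feature_distance = min_feature_distance,
                 tracker = trk, heatmap = hm, rng_seed = rng_seed),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> species=%s band=[%g, %g] Hz window=%gs hop=%gs\n",
              x$species, x$passband_hz[1], x$passband_hz[2],
              x$rr_window_s, x$rr_hop_s))
  cat(sprintf("  features=%d prune=%g%% PCs=%d; tracker: %d particles, %d templates\n",
              x$n_features, x$prune_percentile, x$n_pcs,
              x$tracker$n_particles, x$tracker$n_templates))
  invisible(x)
}

check_config_fps <- function(config, fps) {
  if (config$passband_hz[2] >= fps / 2)
    stop("passband upper edge must be below the Nyquist frequency ", fps / 2, " Hz")
  invisible(config)
}
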