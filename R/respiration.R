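#' Discard unstable trajectories
#'
#' Feature points with poor texture track erratically. Each point's
#' instability is its mean inter-frame displacement magnitude; the
#' `percentile`% most displaced points are discarded, keeping exactly
#' `ceiling((1 - percentile/100) * n)` points (ties broken by point index,
#' lower index kept first).
#'
#' @param traj a `trajectory_matrix` whose points are valid over its whole
#'   frame range (e.g. a window slice).
#' @param percentile percentage of points to discard (default 25).
#' @return The pruned `trajectory_matrix`.
#' @export
prune_unstable <- function(traj, percentile = 25) {
  n <- ncol(traj$x)
  if (n < 4L) stop("need at least 4 valid points before pruning")
  dx <- diff(traj$x); dy <- diff(traj$y)
  instab <- colMeans(sqrt(dx^2 + dy^2))
  keep_n <- ceiling((1 - percentile / 100) * n)
  if (keep_n < 4L) stop("fewer than 4 points would survive pruning")
  keep <- sort(order(instab, seq_len(n))[seq_len(keep_n)])
  structure(list(x = traj$x[, keep, drop = FALSE],
                 y = traj$y[, keep, drop = FALSE],
                 valid = traj$valid[, keep, drop = FALSE],
                 t0_frame = traj$t0_frame,
                 point_index = if (is.null(traj$point_index)) keep
                               else traj$point_index[keep]),
            class = "trajectory_matrix")
}

#' Select the dominant motion axis
#'
#' Splits trajectories into horizontal and vertical components and keeps the
#' axis with the larger total variance after per-point mean removal — the
#' one carrying the main chest movement. Ties break toward the vertical
#' axis (the usual chest direction in a frontal view).
#'
#' @param traj a pruned `trajectory_matrix`.
#' @return Zero-mean numeric matrix (frames x points) with attribute
#'   `"axis"` equal to `"x"` or `"y"`.
#' @export
select_axis <- function(traj) {
  cx <- scale(traj$x, center = TRUE, scale = FALSE)
  cy <- scale(traj$y, center = TRUE, scale = FALSE)
  vx <- sum(colSums(cx^2)) / (nrow(cx) - 1L)
  vy <- sum(colSums(cy^2)) / (nrow(cy) - 1L)
  out <- if (vx > vy) cx else cy
  attr(out, "axis") <- if (vx > vy) "x" else "y"
  out
}

# -------------------------------------------------------------------------

bandpass_cache <- new.env(parent = emptyenv())

#' Design the species band-pass FIR filter
#'
#' Linear-phase equiripple (Parks-McClellan) band-pass filter for the
#' breathing band. Transition width is 0.2 Hz on each side; the design
#' targets 0.35 dB passband ripple and at least 40 dB stopband attenuation
#' (the filter is applied forward-backward, which squares the response, so
#' the effective passband stays within a few percent of unity). The order
#' comes from the standard equiripple estimate `N = A / (22 * df / fs)` and
#' is increased if the realized response misses the attenuation target.
#' Designs are cached per (band, fs).
#'
#' @param passband_hz `c(low, high)` in Hz.
#' @param fs sampling rate (video frame rate), Hz.
#' @param transition_hz transition band width, Hz.
#' @return An object of class `fir_bandpass` with elements `coef`, `order`,
#'   `passband_hz`, `fs`.
#' @export
design_bandpass <- function(passband_hz, fs, transition_hz = 0.2) {
  lo <- passband_hz[1]; hi <- passband_hz[2]
  if (!(0 < lo && lo < hi)) stop("need 0 < low < high")
  if (hi + transition_hz >= fs / 2)
    stop("infeasible band: high + transition must be below fs/2 = ", fs / 2, " Hz")
  if (lo - transition_hz <= 0)
    stop("infeasible band: low - transition must be positive")
  key <- sprintf("%.6g_%.6g_%.6g_%.6g", lo, hi, fs, transition_hz)
  if (!is.null(bandpass_cache[[key]])) return(bandpass_cache[[key]])
  ny <- fs / 2
  atten_db <- 40
  delta_p <- 0.02        # 0.35 dB single-pass ripple
  delta_s <- 10^(-atten_db / 20)
  ord <- ceiling(atten_db / (22 * transition_hz / fs))
  f <- c(0, (lo - transition_hz) / ny, lo / ny, hi / ny, (hi + transition_hz) / ny, 1)
  a <- c(0, 0, 1, 1, 0, 0)
  w <- c(delta_p / delta_s, 1, delta_p / delta_s)
  for (try in 1:4) {
    h <- signal::remez(ord, f, a, w)
    gain <- function(fq) abs(sum(h * exp(-2i * pi * fq / fs * (seq_along(h) - 1))))
    stop_ok <- gain(max(0.01, lo - transition_hz)) <= delta_s * 1.3 &&
               gain(min(ny - 0.01, hi + transition_hz)) <= delta_s * 1.3
    pass_ok <- abs(gain((lo + hi) / 2) - 1) <= 2 * delta_p
    if (stop_ok && pass_ok) break
    ord <- ceiling(ord * 1.2)
  }
  out <- structure(list(coef = as.numeric(h), order = ord,
                        passband_hz = c(lo, hi), fs = fs,
                        transition_hz = transition_hz),
                   class = "fir_bandpass")
  bandpass_cache[[key]] <- out
  out
}

#' @export
print.fir_bandpass <- function(x, ...) {
  cat(sprintf("<fir_bandpass> [%g, %g] Hz @ fs=%g Hz, order %d (equiripple)\n",
              x$passband_hz[1], x$passband_hz[2], x$fs, x$order))
  invisible(x)
}

#' Apply a FIR filter with zero net delay
#'
#' Forward-backward filtering: the signal is convolved with the filter's
#' autocorrelation kernel `conv(h, rev(h))`, whose response is `|H(f)|^2`
#' with exactly zero phase — identical to filtering forward and then
#' backward. Edges are odd-reflection padded to suppress end transients.
#' Columns are filtered independently.
#'
#' @param signals numeric vector or (frames x points) matrix.
#' @param filt a [design_bandpass()] filter.
#' @return Filtered signals, same shape and length.
#' @export
apply_filter <- function(signals, filt) {
  x <- as.matrix(signals)
  n <- nrow(x)
  L <- length(filt$coef)
  if (n <= 3L * filt$order)
    stop("signal too short for filtering: need length > 3 x filter order (",
         3L * filt$order, ")")
  g <- convolve(filt$coef, filt$coef, type = "open")  # conv(h, rev(h))
  P <- L  # reflection pad length
  top <- 2 * x[rep(1L, P), , drop = FALSE] - x[(P + 1L):2L, , drop = FALSE]
  bot <- 2 * x[rep(n, P), , drop = FALSE] - x[(n - 1L):(n - P), , drop = FALSE]
  xp <- rbind(top, x, bot)
  np <- nrow(xp)
  nfft <- stats::nextn(np + length(g) - 1L, c(2L, 3L))
  G <- fft(c(g, rep(0, nfft - length(g))))
  X <- stats::mvfft(rbind(xp, matrix(0, nfft - np, ncol(xp))))
  Y <- Re(stats::mvfft(X * G, inverse = TRUE)) / nfft
  out <- Y[(P + L):(P + L + n - 1L), , drop = FALSE]
  if (is.matrix(signals)) out else drop(out)
}

# -------------------------------------------------------------------------

#' Principal-component decomposition of motion signals
#'
#' Blind source separation of the per-point motion signals: columns are
#' mean-centered and projected onto the leading eigenvectors of their
#' covariance, giving uncorrelated component time series ordered by
#' decreasing explained variance. Only the first few components are needed
#' to carry the chest motion; the default cap is six.
#'
#' @param signals numeric matrix (frames x points), >= 2 columns, >= 8 rows.
#' @param k maximum number of components.
#' @return An object of class `component_set`: `scores` (frames x k'),
#'   `variances` (length k', non-increasing), with `k' = min(k, n_points)`.
#' @export
pca_decompose <- function(signals, k = 6L) {
  x <- as.matrix(signals)
  if (ncol(x) < 2L) stop("need at least 2 signal columns")
  if (nrow(x) < 8L) stop("need at least 8 time samples")
  x <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(x) < 1e-12)) stop("signals have rank 0")
  eg <- eigen(crossprod(x) / (nrow(x) - 1L), symmetric = TRUE)
  kk <- min(k, ncol(x))
  structure(list(scores = x %*% eg$vectors[, seq_len(kk), drop = FALSE],
                 variances = pmax(eg$values[seq_len(kk)], 0)),
            class = "component_set")
}

#' Spectral periodicity score (peak-to-total ratio)
#'
#' The component is Hamming-windowed, zero-padded to a frequency resolution
#' of at most 0.01 Hz, and Fourier transformed. The dominant frequency `f0`
#' is the power-spectrum argmax inside the passband; the score is the power
#' within `halfwidth_hz` of `f0` plus the power within `halfwidth_hz` of its
#' first harmonic `2 f0`, divided by the total power over `(0, fs/2]`. A
#' score near 1 marks a cleanly periodic component, near 0 aperiodic noise.
#'
#' @param component numeric vector (one PCA component over a window).
#' @param fs sampling rate, Hz.
#' @param passband_hz search band for the dominant frequency.
#' @param halfwidth_hz half-width of the peak windows (default 0.05 Hz).
#' @return List with `score` (in `[0, 1]`) and `f0` (Hz).
#' @export
periodicity_score <- function(component, fs, passband_hz, halfwidth_hz = 0.05) {
  n <- length(component)
  if (n < 4 * fs) stop("component must cover at least 4 seconds")
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  xw <- (component - mean(component)) * w
  nfft <- stats::nextn(max(n, ceiling(fs / 0.01)), 2L)
  pw <- Mod(fft(c(xw, rep(0, nfft - n))))^2
  half <- seq_len(nfft %/% 2L)          # bins for (0, fs/2]
  freqs <- half * fs / nfft
  pw <- pw[half + 1L]
  total <- sum(pw)
  if (total <= 0) stop("zero-power component")
  inband <- which(freqs >= passband_hz[1] & freqs <= passband_hz[2])
  if (length(inband) == 0L) stop("no spectral bins inside the passband")
  f0 <- freqs[inband[which.max(pw[inband])]]
  sel <- abs(freqs - f0) <= halfwidth_hz | abs(freqs - 2 * f0) <= halfwidth_hz
  list(score = sum(pw[sel]) / total, f0 = f0)
}

#' Estimate the respiratory rate for one window
#'
#' Scores every component's periodicity, picks the component with the
#' highest score (ties toward the lower index) and converts its dominant
#' frequency to breaths per minute.
#'
#' @param components a [pca_decompose()] result or a numeric matrix of
#'   component time series in columns.
#' @param fs sampling rate, Hz.
#' @param passband_hz breathing band.
#' @param halfwidth_hz peak half-width for the periodicity score.
#' @return List with `rr_bpm`, `pc_index`, `score`, `f0`.
#' @export
estimate_rr_window <- function(components, fs, passband_hz,
                               halfwidth_hz = 0.05) {
  m <- if (inherits(components, "component_set")) components$scores
       else as.matrix(components)
  ps <- lapply(seq_len(ncol(m)), function(j)
    periodicity_score(m[, j], fs, passband_hz, halfwidth_hz))
  scores <- vapply(ps, `[[`, 0, "score")
  best <- which.max(scores)
  list(rr_bpm = 60 * ps[[best]]$f0, pc_index = best,
       score = scores[best], f0 = ps[[best]]$f0)
}

# -------------------------------------------------------------------------

#' Estimate a respiratory-rate trace from a thermal video
#'
#' Runs the full chain on sliding windows: per-frame contrast stretch,
#' animal segmentation (multilevel Otsu, first frame), Shi-Tomasi feature
#' detection inside the thorax ROI (first frame only), pyramidal
#' Lucas-Kanade tracking through the whole video, band-pass filtering of the
#' trajectories to the species band, and then per window of `rr_window_s`
#' seconds (hopped every `rr_hop_s`): pruning of the most displaced
#' trajectory quartile, dominant-axis selection, PCA source separation and
#' periodicity-based rate estimation. `rr_bpm_median` is the median of the
#' estimates in the trailing `median_s` seconds, which suppresses single
#' outlier windows at the cost of a slight delay. On videos shorter than
#' three filter lengths the band-pass transition band widens proportionally
#' so the filter still fits the data.
#'
#' @param video a [thermal_video()].
#' @param roi thorax [rect_roi()].
#' @param config a [run_config()].
#' @return An object of class `rr_trace`: a data frame with columns
#'   `time_s` (window end), `rr_bpm`, `rr_bpm_median`, `periodicity`,
#'   `pc_index`, `valid`; windows whose estimation failed appear as invalid
#'   gap rows.
#' @export
rr_trace <- function(video, roi, config = run_config("rat")) {
  stopifnot(inherits(video, "thermal_video"))
  fps <- video$fps
  check_roi(roi, dim(video$frames))
  check_config_fps(config, fps)
  nf <- n_frames(video)
  win_n <- round(config$rr_window_s * fps)
  hop_n <- max(1L, round(config$rr_hop_s * fps))
  if (nf < win_n) stop("video shorter than one analysis window")

  video8 <- cpp_stretch_video(video$frames, config$stretch_lo_pct,
                              config$stretch_hi_pct)
  seg <- segment_animal(video$frames[, , 1L],
                        multilevel_otsu(video$frames[, , 1L], config$otsu_classes))
  mask <- if (seg$empty) NULL else seg$mask
  pts <- detect_features(video8[, , 1L], roi, mask, config$n_features,
                         config$min_feature_distance)
  # track on a padded crop around the ROI: points never leave the thorax
  # neighborhood and the pyramid work drops with the frame area
  d <- dim(video8)
  pad <- 24L
  cx0 <- max(0L, roi$x0 - pad); cx1 <- min(d[2], roi$x1 + pad)
  cy0 <- max(0L, roi$y0 - pad); cy1 <- min(d[1], roi$y1 + pad)
  crop <- video8[(cy0 + 1L):cy1, (cx0 + 1L):cx1, , drop = FALSE]
  pts_c <- cbind(x = pts[, 1] - cx0, y = pts[, 2] - cy0)
  traj <- track_features(crop, pts_c)
  traj$x <- traj$x + cx0
  traj$y <- traj$y + cy0

  # short videos cannot carry the default 0.2 Hz transition band (filter
  # length must stay under a third of the signal); widen proportionally
  filt <- design_bandpass(config$passband_hz, fps)
  if (nf <= 3L * filt$order) {
    ord_max <- (nf - 1L) %/% 3L
    tw <- 40 * fps / (22 * ord_max) * 1.05
    filt <- design_bandpass(config$passband_hz, fps, transition_hz = tw)
    if (nf <= 3L * filt$order)
      stop("video too short for band-pass filtering in this band")
  }
  # filter each point over its valid span (spans start at frame 1)
  npts <- ncol(traj$x)
  fx <- matrix(NA_real_, nf, npts); fy <- matrix(NA_real_, nf, npts)
  span <- vapply(seq_len(npts), function(j) {
    v <- traj$valid[, j]
    if (all(v)) nf else max(0L, which(!v)[1L] - 1L)
  }, 0L)
  full <- span == nf & nf > 3L * filt$order
  if (any(full)) {  # batch the common case: points valid through the video
    fx[, full] <- apply_filter(traj$x[, full, drop = FALSE], filt)
    fy[, full] <- apply_filter(traj$y[, full, drop = FALSE], filt)
  }
  for (j in which(!full)) {
    if (span[j] > 3L * filt$order) {
      fx[seq_len(span[j]), j] <- apply_filter(traj$x[seq_len(span[j]), j], filt)
      fy[seq_len(span[j]), j] <- apply_filter(traj$y[seq_len(span[j]), j], filt)
    }
  }

  ends <- seq(win_n, nf, by = hop_n)
  nw <- length(ends)
  rr <- rep(NA_real_, nw); per <- rep(NA_real_, nw)
  pci <- rep(NA_integer_, nw); win_valid <- logical(nw)
  for (i in seq_len(nw)) {
    e <- ends[i]
    a <- e - win_n + 1L
    est <- tryCatch({
      tr <- slice_trajectories(traj, a, e)
      # keep only points that also have a filtered signal (long enough span)
      ok <- span[tr$point_index] > 3L * filt$order
      if (sum(ok) < 4L) stop("too few valid points in window")
      tr$x <- tr$x[, ok, drop = FALSE]
      tr$y <- tr$y[, ok, drop = FALSE]
      tr$valid <- tr$valid[, ok, drop = FALSE]
      tr$point_index <- tr$point_index[ok]
      pruned <- prune_unstable(tr, config$prune_percentile)
      ax <- attr(select_axis(pruned), "axis")
      fmat <- if (ax == "x") fx else fy
      sig <- fmat[a:e, pruned$point_index, drop = FALSE]
      sig <- scale(sig, center = TRUE, scale = FALSE)
      comps <- pca_decompose(sig, config$n_pcs)
      estimate_rr_window(comps, fps, config$passband_hz,
                         config$harmonic_halfwidth_hz)
    }, error = function(err) NULL)
    if (!is.null(est)) {
      rr[i] <- est$rr_bpm; per[i] <- est$score
      pci[i] <- est$pc_index; win_valid[i] <- TRUE
    }
  }
  out <- data.frame(time_s = ends / fps, rr_bpm = rr, periodicity = per,
                    pc_index = pci, valid = win_valid)
  out$rr_bpm_median <- vapply(seq_len(nrow(out)), function(i) {
    sel <- out$valid & out$time_s > out$time_s[i] - config$median_s &
      out$time_s <= out$time_s[i]
    if (!any(sel)) NA_real_ else median(out$rr_bpm[sel])
  }, 0)
  out <- out[, c("time_s", "rr_bpm", "rr_bpm_median", "periodicity",
                 "pc_index", "valid")]
  structure(out, class = c("rr_trace", "data.frame"),
            fps = fps, config = config, n_points = npts)
}

#' @export
print.rr_trace <- function(x, ...) {
  ok <- x$valid
  cat(sprintf("<rr_trace> %d windows (%d valid), t = %.1f..%.1f s\n",
              nrow(x), sum(ok), min(x$time_s), max(x$time_s)))
  if (any(ok))
    cat(sprintf("  rr_bpm_median: %.1f-%.1f (median %.1f), periodicity %.2f-%.2f\n",
                min(x$rr_bpm_median[ok]), max(x$rr_bpm_median[ok]),
                median(x$rr_bpm_median[ok]),
                min(x$periodicity[ok]), max(x$periodicity[ok])))
  invisible(x)
}

#' @export
summary.rr_trace <- function(object, ...) {
  ok <- object$valid
  res <- list(n_windows = nrow(object), n_valid = sum(ok),
              rr_mean = mean(object$rr_bpm_median[ok]),
              rr_sd = sd(object$rr_bpm_median[ok]),
              rr_range = range(object$rr_bpm_median[ok]),
              periodicity_median = median(object$periodicity[ok]))
  class(res) <- "summary.rr_trace"
  res
}

#' @export
print.summary.rr_trace <- function(x, ...) {
  cat(sprintf("Respiratory-rate trace: %d/%d valid windows\n", x$n_valid, x$n_windows))
  cat(sprintf("  RR (median-smoothed): %.2f +/- %.2f breaths/min, range %.2f-%.2f\n",
              x$rr_mean, x$rr_sd, x$rr_range[1], x$rr_range[2]))
  cat(sprintf("  median periodicity score: %.3f\n", x$periodicity_median))
  invisible(x)
}

#' @export
plot.rr_trace <- function(x, ..., truth = NULL) {
  ok <- x$valid
  graphics::plot(x$time_s[ok], x$rr_bpm[ok], type = "p", pch = 16, cex = 0.5,
                 col = "grey60", xlab = "time [s]",
                 ylab = "respiratory rate [breaths/min]", ...)
  graphics::lines(x$time_s[ok], x$rr_bpm_median[ok], col = "firebrick", lwd = 2)
  if (!is.null(truth))
    graphics::lines(truth$time_s, truth$rr_bpm, col = "navy", lty = 2)
  graphics::legend("topright", bty = "n",
                   legend = c("per window", "5-s median", if (!is.null(truth)) "truth"),
                   col = c("grey60", "firebrick", if (!is.null(truth)) "navy"),
                   pch = c(16, NA, if (!is.null(truth)) NA),
                   lty = c(NA, 1, if (!is.null(truth)) 2))
  invisible(x)
}

# -------------------------------------------------------------------------

#' Agreement metrics against a reference trace
#'
#' Pairs the estimated trace with a reference by nearest timestamp (within
#' half the estimate's hop) and computes the standard agreement panel:
#' root-mean-square error, mean and 90th-percentile relative error (in %),
#' Pearson correlation, and Bland-Altman bias with 95% limits of agreement.
#'
#' @param est_trace an [rr_trace()] or data frame with `time_s` and a rate
#'   column.
#' @param ref_trace data frame with `time_s` and `rr_bpm` (reference rates,
#'   all > 0).
#' @param estimate which estimate column to evaluate: the median-smoothed
#'   rate (default) or the raw per-window rate.
#' @return An object of class `rr_agreement` with fields `rmse_bpm`,
#'   `mean_rel_err_pct`, `p90_rel_err_pct`, `pearson_r`,
#'   `bland_altman_bias_bpm`, `loa_low_bpm`, `loa_high_bpm`, `n_pairs`.
#' @export
evaluate_against_reference <- function(est_trace, ref_trace,
                                       estimate = c("median", "raw")) {
  estimate <- match.arg(estimate)
  col <- if (inherits(est_trace, "rr_trace") || "rr_bpm_median" %in% names(est_trace)) {
    if (estimate == "median") "rr_bpm_median" else "rr_bpm"
  } else "rr_bpm"
  et <- est_trace$time_s
  ev <- est_trace[[col]]
  keep <- is.finite(ev)
  if ("valid" %in% names(est_trace)) keep <- keep & est_trace$valid
  et <- et[keep]; ev <- ev[keep]
  hop <- if (length(et) > 1L) min(diff(sort(et))) else 1
  idx <- vapply(et, function(t) which.min(abs(ref_trace$time_s - t)), 0L)
  good <- abs(ref_trace$time_s[idx] - et) <= hop / 2
  est <- ev[good]
  ref <- ref_trace$rr_bpm[idx[good]]
  if (length(est) < 3L) stop("need at least 3 matched estimate/reference pairs")
  if (any(ref <= 0)) stop("reference rates must be positive")
  d <- est - ref
  rel <- 100 * abs(d) / ref
  structure(list(rmse_bpm = sqrt(mean(d^2)),
                 mean_rel_err_pct = mean(rel),
                 p90_rel_err_pct = quantile(rel, 0.9, names = FALSE),
                 pearson_r = if (sd(est) > 0 && sd(ref) > 0) cor(est, ref) else NA_real_,
                 bland_altman_bias_bpm = mean(d),
                 loa_low_bpm = mean(d) - 1.96 * sd(d),
                 loa_high_bpm = mean(d) + 1.96 * sd(d),
                 n_pairs = length(est)),
            class = "rr_agreement")
}

#' @export
print.rr_agreement <- function(x, ...) {
  cat(sprintf("<rr_agreement> over %d pairs\n", x$n_pairs))
  cat(sprintf("  RMSE            %.3f breaths/min\n", x$rmse_bpm))
  cat(sprintf("  mean rel. error %.3f %%  (90th pct %.3f %%)\n",
              x$mean_rel_err_pct, x$p90_rel_err_pct))
  cat(sprintf("  Pearson r       %.4f\n", x$pearson_r))
  cat(sprintf("  Bland-Altman    bias %.3f, LoA [%.3f, %.3f] breaths/min\n",
              x$bland_altman_bias_bpm, x$loa_low_bpm, x$loa_high_bpm))
  invisible(x)
}
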