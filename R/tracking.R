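#' Zero-mean, unit-norm patch normalization
#'
#' The normalization applied to every template and candidate patch before
#' sparse coding. Errors on zero-variance (textureless) patches.
#'
#' @param p numeric vector (flattened patch).
#' @return Normalized numeric vector with mean 0 and l2 norm 1.
#' @export
normalize_patch <- function(p) {
  p <- p - mean(p)
  nrm <- sqrt(sum(p^2))
  if (nrm < 1e-8) stop("zero-variance patch")
  p / nrm
}

#' Initialize the sparse-representation tracker
#'
#' Builds the template library from the first frame: the ROI patch plus
#' one-pixel-shifted copies of it (robustness to the initial alignment),
#' each downsampled to the tracker patch size, zero-meaned and unit-normed.
#' Particles start at the ROI state with Gaussian jitter. The state space is
#' `(cx, cy, log sx, log sy)`: a top-down warm rodent blob is nearly
#' rotation-invariant at patch scale, so translation plus anisotropic scale
#' suffices and keeps the particle count low.
#'
#' @param frame8 integer matrix (0-255), first video frame after contrast
#'   stretch.
#' @param roi animal [rect_roi()] in the first frame.
#' @param config a [run_config()]; see its `tracker` sub-list.
#' @param seed RNG seed (defaults to `config$rng_seed`); the same seed gives
#'   bit-identical tracking.
#' @return An object of class `tracker_state`.
#' @export
init_tracker <- function(frame8, roi, config = run_config("rat"),
                         seed = config$rng_seed) {
  check_roi(roi, dim(frame8))
  trk <- config$tracker
  ph <- trk$patch[1]; pw <- trk$patch[2]
  w0 <- roi$x1 - roi$x0; h0 <- roi$y1 - roi$y0
  if (w0 * h0 < 64) stop("ROI patch too small: need area >= 64 px")
  set.seed(seed)
  storage.mode(frame8) <- "integer"
  cx <- (roi$x0 + roi$x1 - 1) / 2
  cy <- (roi$y0 + roi$y1 - 1) / 2
  # ROI patch plus its one-pixel-shifted copies (cycled if m > 9)
  shifts <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                  c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  m <- trk$n_templates
  templates <- vapply(seq_len(m), function(i) {
    s <- shifts[(i - 1L) %% nrow(shifts) + 1L, ]
    normalize_patch(cpp_extract_patch(frame8, cx + s[1], cy + s[2],
                                      w0, h0, ph, pw))
  }, numeric(ph * pw))
  np <- trk$n_particles
  particles <- cbind(cx = cx + rnorm(np, 0, trk$sigma_xy),
                     cy = cy + rnorm(np, 0, trk$sigma_xy),
                     log_sx = rnorm(np, 0, trk$sigma_scale),
                     log_sy = rnorm(np, 0, trk$sigma_scale))
  structure(list(particles = particles, weights = rep(1 / np, np),
                 templates = templates,
                 template_importance = rep(1 / m, m),
                 w0 = w0, h0 = h0, frame_dim = dim(frame8),
                 config = trk, frame_index = 1L),
            class = "tracker_state")
}

#' @export
print.tracker_state <- function(x, ...) {
  cat(sprintf("<tracker_state> frame %d, %d particles, %d templates (%dx%d patch)\n",
              x$frame_index, nrow(x$particles), ncol(x$templates),
              x$config$patch[1], x$config$patch[2]))
  invisible(x)
}

#' Propagate particles through the state-transition model
#'
#' Each particle is perturbed by zero-mean Gaussian noise: `sigma_xy` pixels
#' on the center, `sigma_scale` on the log-scales. Centers are clipped to
#' the frame bounds.
#'
#' @param state a `tracker_state`.
#' @return Candidate state matrix (n_particles x 4).
#' @export
propagate <- function(state) {
  p <- state$particles
  np <- nrow(p)
  trk <- state$config
  cand <- cbind(p[, 1] + rnorm(np, 0, trk$sigma_xy),
                p[, 2] + rnorm(np, 0, trk$sigma_xy),
                p[, 3] + rnorm(np, 0, trk$sigma_scale),
                p[, 4] + rnorm(np, 0, trk$sigma_scale))
  cand[, 1] <- pmin(pmax(cand[, 1], 0), state$frame_dim[2] - 1)
  cand[, 2] <- pmin(pmax(cand[, 2], 0), state$frame_dim[1] - 1)
  colnames(cand) <- colnames(p)
  cand
}

#' Sparse reconstruction of a candidate patch
#'
#' Solves the non-negative l1-regularized least-squares problem over the
#' dictionary of target templates plus positive and negative trivial
#' (identity) templates,
#' `min ||y - [T, I, -I] c||^2 + lambda ||c||_1, c >= 0`,
#' by cyclic coordinate descent. The reconstruction error reported for
#' tracking uses the target-template coefficients only: trivial templates
#' absorb occlusion and clutter, so a candidate explained mostly by trivial
#' templates scores a large error.
#'
#' @param candidate_patch numeric vector, zero-mean unit-norm like the
#'   templates (use [normalize_patch()] semantics).
#' @param templates matrix with unit-norm template columns.
#' @param lambda l1 penalty weight.
#' @param tol,maxit coordinate-descent convergence tolerance and sweep cap.
#' @return List with `coef` (target coefficients), `trivial` (net trivial
#'   coefficients, sign = positive minus negative template), `error`
#'   (`||y - T c_T||^2`) and `objective`.
#' @export
sparse_reconstruct <- function(candidate_patch, templates, lambda = 0.01,
                               tol = 1e-6, maxit = 1000L) {
  stopifnot(length(candidate_patch) == nrow(templates))
  cpp_l1_solve(as.numeric(candidate_patch), templates, lambda, tol,
               as.integer(maxit))
}

#' Advance the tracker by one frame
#'
#' Propagates the particles, scores every candidate by its sparse
#' reconstruction error, takes the smallest-error candidate as the tracking
#' result, reweights particles by `exp(-alpha * error)` and resamples
#' (systematic) when the effective sample size drops below half the particle
#' count.
#'
#' @param state a `tracker_state`.
#' @param frame8 integer matrix (0-255) of the next frame.
#' @return List with `state` (advanced) and `result` (one-row data frame:
#'   `frame`, `x_px`, `y_px`, `sx`, `sy`, `error`).
#' @export
track_step <- function(state, frame8) {
  trk <- state$config
  storage.mode(frame8) <- "integer"
  cand <- propagate(state)
  errs <- cpp_score_candidates(frame8, cand, state$w0, state$h0,
                               state$templates, trk$lambda, trk$tol,
                               as.integer(trk$maxit),
                               trk$patch[1], trk$patch[2])
  best <- which.min(errs)
  w <- exp(-trk$alpha * (errs - min(errs)))
  w <- w / sum(w)
  np <- nrow(cand)
  ess <- 1 / sum(w^2)
  if (ess < np / 2) {
    u <- (runif(1) + seq_len(np) - 1) / np
    idx <- findInterval(u, cumsum(w)) + 1L
    idx[idx > np] <- np
    particles <- cand[idx, , drop = FALSE]
    weights <- rep(1 / np, np)
  } else {
    particles <- cand
    weights <- w
  }
  state$particles <- particles
  state$weights <- weights
  state$frame_index <- state$frame_index + 1L
  result <- data.frame(frame = state$frame_index,
                       x_px = cand[best, 1], y_px = cand[best, 2],
                       sx = exp(cand[best, 3]), sy = exp(cand[best, 4]),
                       error = errs[best])
  list(state = state, result = result)
}

#' Update the template library
#'
#' If the result patch is still similar (cosine similarity >= `tau`) to some
#' template, that template's importance increases; otherwise the appearance
#' has drifted and the lowest-importance template is replaced by the result
#' patch. Importance weights renormalize to 1.
#'
#' @param state a `tracker_state`.
#' @param result_patch zero-mean unit-norm patch of the tracking result.
#' @return The updated `tracker_state`.
#' @export
update_templates <- function(state, result_patch) {
  sims <- as.numeric(crossprod(state$templates, result_patch))
  tau <- state$config$tau
  imp <- state$template_importance
  if (max(sims) < tau) {
    j <- which.min(imp)
    state$templates[, j] <- result_patch
    imp[j] <- mean(imp)
  } else {
    j <- which.max(sims)
    imp[j] <- imp[j] + 0.1 * max(imp)
  }
  state$template_importance <- imp / sum(imp)
  state
}

#' Track the animal through a thermal video
#'
#' Contrast-stretches every frame, initializes the sparse-representation
#' particle filter on the first frame, then steps through the video with
#' template updating. Rows whose reconstruction error exceeds five times the
#' running median error are flagged low-confidence.
#'
#' @param video a [thermal_video()].
#' @param roi animal [rect_roi()] in the first frame.
#' @param config a [run_config()].
#' @return An object of class `oft_track`: data frame with columns `frame`
#'   (1-based), `time_s`, `x_px`, `y_px`, `sx`, `sy`, `error`,
#'   `low_confidence`.
#' @export
track_video <- function(video, roi, config = run_config("rat")) {
  stopifnot(inherits(video, "thermal_video"))
  nf <- n_frames(video)
  if (nf < 2L) stop("need at least 2 frames")
  video8 <- cpp_stretch_video(video$frames, config$stretch_lo_pct,
                              config$stretch_hi_pct)
  state <- init_tracker(video8[, , 1L], roi, config)
  trk <- config$tracker
  rows <- vector("list", nf)
  rows[[1L]] <- data.frame(frame = 1L,
                           x_px = (roi$x0 + roi$x1 - 1) / 2,
                           y_px = (roi$y0 + roi$y1 - 1) / 2,
                           sx = 1, sy = 1, error = 0)
  for (t in 2:nf) {
    fr <- video8[, , t]
    st <- track_step(state, fr)
    state <- st$state
    res <- st$result
    res$frame <- t
    patch <- tryCatch(
      normalize_patch(cpp_extract_patch(fr, res$x_px, res$y_px,
                                        state$w0 * res$sx, state$h0 * res$sy,
                                        trk$patch[1], trk$patch[2])),
      error = function(e) NULL)
    if (!is.null(patch)) state <- update_templates(state, patch)
    rows[[t]] <- res
  }
  out <- do.call(rbind, rows)
  out$time_s <- (out$frame - 1) / video$fps
  run_med <- vapply(seq_len(nf), function(i)
    median(out$error[max(1L, i - 30L):i]), 0)
  out$low_confidence <- out$error > 5 * pmax(run_med, 1e-6)
  out <- out[, c("frame", "time_s", "x_px", "y_px", "sx", "sy",
                 "error", "low_confidence")]
  structure(out, class = c("oft_track", "data.frame"),
            fps = video$fps, roi = roi)
}

#' @export
print.oft_track <- function(x, ...) {
  cat(sprintf("<oft_track> %d frames (%.1f s), %d low-confidence\n",
              nrow(x), max(x$time_s), sum(x$low_confidence)))
  cat(sprintf("  x: %.1f-%.1f px, y: %.1f-%.1f px, median error %.4f\n",
              min(x$x_px), max(x$x_px), min(x$y_px), max(x$y_px),
              median(x$error)))
  invisible(x)
}

#' @export
plot.oft_track <- function(x, ..., truth = NULL) {
  graphics::plot(x$x_px, x$y_px, type = "l", col = "firebrick",
                 xlab = "x [px]", ylab = "y [px]", ylim = rev(range(x$y_px)),
                 asp = 1, ...)
  if (!is.null(truth))
    graphics::lines(truth$x_px, truth$y_px, col = "navy", lty = 2)
  invisible(x)
}
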