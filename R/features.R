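#' Detect Shi-Tomasi feature points
#'
#' Scores every pixel by the minimum eigenvalue of the local gradient
#' structure tensor (summed over a small box window) and greedily keeps the
#' highest-scoring points inside `roi` (and `mask`, if given), enforcing a
#' minimum mutual distance. Detection is meant to run on the first frame
#' only; the points are then handed to [track_features()].
#'
#' @param frame8 integer matrix (0-255), e.g. from [stretch_contrast()].
#' @param roi a [rect_roi()].
#' @param mask optional logical matrix restricting candidate pixels
#'   (typically the foreground from [segment_animal()]).
#' @param n maximum number of points.
#' @param min_distance minimum mutual Euclidean distance in px.
#' @return A two-column matrix `(x, y)` of 0-based positions, ranked by
#'   decreasing corner response. Fewer than 4 detectable points is an error
#'   (insufficient texture).
#' @export
detect_features <- function(frame8, roi, mask = NULL, n = 100,
                            min_distance = 2) {
  check_roi(roi, dim(frame8))
  resp <- cpp_shi_tomasi(matrix(as.numeric(frame8), nrow(frame8)), 2L)
  keep <- matrix(FALSE, nrow(frame8), ncol(frame8))
  keep[(roi$y0 + 1):roi$y1, (roi$x0 + 1):roi$x1] <- TRUE
  if (!is.null(mask)) keep <- keep & mask
  resp[!keep] <- 0
  idx <- which(resp > 0)
  if (length(idx) < 4L) stop("insufficient texture: fewer than 4 corner candidates in ROI")
  idx <- idx[order(resp[idx], decreasing = TRUE)]
  ys <- (idx - 1L) %% nrow(resp)      # 0-based row
  xs <- (idx - 1L) %/% nrow(resp)     # 0-based col
  selx <- numeric(0); sely <- numeric(0)
  md2 <- min_distance^2
  for (i in seq_along(idx)) {
    if (length(selx) >= n) break
    if (length(selx) == 0L ||
        all((selx - xs[i])^2 + (sely - ys[i])^2 >= md2)) {
      selx <- c(selx, xs[i]); sely <- c(sely, ys[i])
    }
  }
  if (length(selx) < 4L) stop("insufficient texture: fewer than 4 feature points found")
  cbind(x = selx, y = sely)
}

#' Track feature points with pyramidal Lucas-Kanade optical flow
#'
#' Propagates each point frame-to-frame by iterative Lucas-Kanade estimation
#' on a 2-level image pyramid. A point whose flow fails (window leaves the
#' frame, singular gradient matrix, or the iteration diverges out of bounds)
#' is marked invalid from that frame on.
#'
#' @param video8 integer array (rows, cols, frames) of 8-bit frames.
#' @param points start positions from [detect_features()].
#' @param window_halfwidth half-width of the tracking window in px (window
#'   is `2w+1` squared).
#' @param levels pyramid levels.
#' @param max_iter,eps iteration cap and convergence threshold (px).
#' @return An object of class `trajectory_matrix`: list with `x`, `y`
#'   (frames x points positions), `valid` (frames x points logical) and
#'   `t0_frame`.
#' @export
track_features <- function(video8, points, window_halfwidth = 5L,
                           levels = 2L, max_iter = 5L, eps = 0.02) {
  stopifnot(is.array(video8), length(dim(video8)) == 3L)
  storage.mode(video8) <- "integer"
  res <- cpp_lk_track(video8, points[, 1], points[, 2],
                      as.integer(levels), as.integer(window_halfwidth),
                      as.integer(max_iter), eps)
  traj <- structure(list(x = res$x, y = res$y, valid = res$valid, t0_frame = 0L),
                    class = "trajectory_matrix")
  if (sum(traj$valid[nrow(traj$valid), ]) < 1L)
    stop("all feature points lost before the end of the video")
  traj
}

#' @export
print.trajectory_matrix <- function(x, ...) {
  cat(sprintf("<trajectory_matrix> %d frames x %d points (%d valid at end)\n",
              nrow(x$x), ncol(x$x), sum(x$valid[nrow(x$valid), ])))
  invisible(x)
}

# subset a trajectory matrix to a frame range, keeping only points valid
# throughout the range
slice_trajectories <- function(traj, from, to) {
  ok <- colSums(!traj$valid[from:to, , drop = FALSE]) == 0L
  structure(list(x = traj$x[from:to, ok, drop = FALSE],
                 y = traj$y[from:to, ok, drop = FALSE],
                 valid = traj$valid[from:to, ok, drop = FALSE],
                 t0_frame = traj$t0_frame + from - 1L,
                 point_index = which(ok)),
            class = "trajectory_matrix")
}
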