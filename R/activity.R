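#' Arena calibration
#'
#' Maps pixel coordinates to arena millimetres: the arena rectangle in the
#' frame (a [rect_roi()]) corresponds to the physical arena of
#' `arena_w_mm` x `arena_h_mm`.
#'
#' @param arena_w_mm,arena_h_mm physical arena size in mm.
#' @param arena_px arena rectangle in the frame, a [rect_roi()].
#' @return An object of class `arena_calibration` with mm-per-pixel scales.
#' @export
arena_calibration <- function(arena_w_mm, arena_h_mm, arena_px) {
  stopifnot(arena_w_mm > 0, arena_h_mm > 0, inherits(arena_px, "rect_roi"))
  structure(list(arena_w_mm = arena_w_mm, arena_h_mm = arena_h_mm,
                 arena_px = arena_px,
                 mm_per_px_x = arena_w_mm / (arena_px$x1 - arena_px$x0),
                 mm_per_px_y = arena_h_mm / (arena_px$y1 - arena_px$y0)),
            class = "arena_calibration")
}

#' @export
print.arena_calibration <- function(x, ...) {
  cat(sprintf("<arena_calibration> %g x %g mm, %.3f / %.3f mm per px (x/y)\n",
              x$arena_w_mm, x$arena_h_mm, x$mm_per_px_x, x$mm_per_px_y))
  invisible(x)
}

# pixel track -> arena mm coordinates (clipped to the arena, with a warning
# when clipping was needed)
track_to_mm <- function(track, calib, warn = TRUE) {
  px <- track$x_px - calib$arena_px$x0
  py <- track$y_px - calib$arena_px$y0
  xmm <- px * calib$mm_per_px_x
  ymm <- py * calib$mm_per_px_y
  out_of <- xmm < 0 | xmm > calib$arena_w_mm | ymm < 0 | ymm > calib$arena_h_mm
  if (any(out_of) && warn)
    warning(sum(out_of), " track positions outside the arena were clipped")
  data.frame(time_s = track$time_s,
             x_mm = pmin(pmax(xmm, 0), calib$arena_w_mm),
             y_mm = pmin(pmax(ymm, 0), calib$arena_h_mm))
}

#' Animal speed over time
#'
#' Central finite difference of the mm-converted positions (one-sided at the
#' endpoints), followed by a moving average over `smooth_s` seconds to
#' suppress tracker jitter.
#'
#' @param track an [track_video()] result (or data frame with `time_s`,
#'   `x_px`, `y_px`).
#' @param calib an [arena_calibration()].
#' @param smooth_s moving-average window in seconds (0 disables smoothing).
#' @return Numeric vector of speeds in mm/s, one per frame.
#' @export
velocity <- function(track, calib, smooth_s = 0.5) {
  if (nrow(track) < 3L) stop("need at least 3 frames")
  mm <- track_to_mm(track, calib, warn = FALSE)
  n <- nrow(mm)
  t <- mm$time_s
  vx <- numeric(n); vy <- numeric(n)
  i <- 2:(n - 1)
  vx[i] <- (mm$x_mm[i + 1] - mm$x_mm[i - 1]) / (t[i + 1] - t[i - 1])
  vy[i] <- (mm$y_mm[i + 1] - mm$y_mm[i - 1]) / (t[i + 1] - t[i - 1])
  vx[1] <- (mm$x_mm[2] - mm$x_mm[1]) / (t[2] - t[1])
  vy[1] <- (mm$y_mm[2] - mm$y_mm[1]) / (t[2] - t[1])
  vx[n] <- (mm$x_mm[n] - mm$x_mm[n - 1]) / (t[n] - t[n - 1])
  vy[n] <- (mm$y_mm[n] - mm$y_mm[n - 1]) / (t[n] - t[n - 1])
  sp <- sqrt(vx^2 + vy^2)
  fps <- 1 / median(diff(t))
  k <- max(1L, round(smooth_s * fps))
  if (k > 1L) {
    kern <- rep(1 / k, k)
    sp <- as.numeric(stats::filter(sp, kern, sides = 2))
    # one-sided means at the ends where the centered window is incomplete
    na <- which(is.na(sp))
    for (j in na) {
      a <- max(1L, j - k %/% 2L); b <- min(n, j + k %/% 2L)
      sp[j] <- mean(sqrt(vx[a:b]^2 + vy[a:b]^2))
    }
  }
  sp
}

#' Occupancy heat map
#'
#' Divides the arena into `grid_n` x `grid_n` cells and accumulates the time
#' (one frame period per frame) in the cell containing the animal center.
#' The cell sum always equals the track duration: positions outside the
#' arena are clipped (with a warning).
#'
#' @param track an [track_video()] result.
#' @param calib an [arena_calibration()].
#' @param grid_n grid size per axis (>= 2).
#' @return An `occupancy_map`: `grid_n` x `grid_n` numeric matrix of
#'   seconds (rows = arena y), with attributes `cell_mm` and `duration_s`.
#' @export
occupancy_heatmap <- function(track, calib, grid_n = 32L) {
  if (grid_n < 2L) stop("`grid_n` must be at least 2")
  mm <- track_to_mm(track, calib)
  fps <- 1 / median(diff(mm$time_s))
  ix <- pmin(grid_n, pmax(1L, floor(mm$x_mm / calib$arena_w_mm * grid_n) + 1L))
  iy <- pmin(grid_n, pmax(1L, floor(mm$y_mm / calib$arena_h_mm * grid_n) + 1L))
  grid <- matrix(0, grid_n, grid_n)
  for (i in seq_along(ix)) grid[iy[i], ix[i]] <- grid[iy[i], ix[i]] + 1
  grid <- grid / fps
  structure(grid, class = c("occupancy_map", "matrix"),
            cell_mm = c(calib$arena_w_mm / grid_n, calib$arena_h_mm / grid_n),
            duration_s = nrow(mm) / fps)
}

#' @export
print.occupancy_map <- function(x, ...) {
  cat(sprintf("<occupancy_map> %d x %d cells of %.1f x %.1f mm, total %.2f s\n",
              nrow(x), ncol(x), attr(x, "cell_mm")[1], attr(x, "cell_mm")[2],
              sum(x)))
  invisible(x)
}

#' Logarithmic occupancy map
#'
#' `log(1 + seconds)` per cell: order-preserving, zeros stay zero, and
#' rarely visited paths that vanish in the linear map become visible.
#'
#' @param map an [occupancy_heatmap()] result.
#' @return The transformed map (same class and attributes).
#' @export
log_heatmap <- function(map) {
  out <- log1p(unclass(map))
  attributes(out) <- attributes(map)
  out
}

#' Zone and activity metrics for an open-field track
#'
#' The center zone is the concentric rectangle whose sides are
#' `center_frac` of the arena sides (the conventional 50% linear / 25% area
#' center). Distances are summed from frame-to-frame displacements and
#' attributed to the zone of the segment start; immobility is the total
#' length of maximal runs with smoothed speed below `immobility_speed`
#' lasting at least `immobility_min_s`.
#'
#' @param track an [track_video()] result.
#' @param calib an [arena_calibration()].
#' @param center_frac linear fraction of each arena side forming the center
#'   zone.
#' @param immobility_speed speed threshold in mm/s.
#' @param immobility_min_s minimum immobile run length in seconds.
#' @return An object of class `activity_summary` (one-row data frame) with
#'   `total_distance_mm`, `mean_speed_mm_s`, `max_speed_mm_s`,
#'   `time_center_s`, `time_periphery_s`, `distance_center_mm`,
#'   `distance_periphery_mm`, `immobility_time_s`, `duration_s`.
#' @export
zone_metrics <- function(track, calib, center_frac = 0.5,
                         immobility_speed = 5, immobility_min_s = 1) {
  if (nrow(track) < 2L) stop("need at least 2 frames")
  mm <- track_to_mm(track, calib, warn = FALSE)
  n <- nrow(mm)
  fps <- 1 / median(diff(mm$time_s))
  dt <- 1 / fps
  dx <- diff(mm$x_mm); dy <- diff(mm$y_mm)
  seg <- sqrt(dx^2 + dy^2)
  cw <- calib$arena_w_mm * center_frac
  ch <- calib$arena_h_mm * center_frac
  in_center <- mm$x_mm >= (calib$arena_w_mm - cw) / 2 &
    mm$x_mm <= (calib$arena_w_mm + cw) / 2 &
    mm$y_mm >= (calib$arena_h_mm - ch) / 2 &
    mm$y_mm <= (calib$arena_h_mm + ch) / 2
  sp <- velocity(track, calib)
  slow <- sp < immobility_speed
  r <- rle(slow)
  immobile <- sum(r$lengths[r$values & r$lengths * dt >= immobility_min_s]) * dt
  out <- data.frame(total_distance_mm = sum(seg),
                    mean_speed_mm_s = mean(sp),
                    max_speed_mm_s = max(sp),
                    time_center_s = sum(in_center) * dt,
                    time_periphery_s = sum(!in_center) * dt,
                    distance_center_mm = sum(seg[in_center[-n]]),
                    distance_periphery_mm = sum(seg[!in_center[-n]]),
                    immobility_time_s = immobile,
                    duration_s = n * dt)
  structure(out, class = c("activity_summary", "data.frame"))
}

#' @export
print.activity_summary <- function(x, ...) {
  cat("<activity_summary>\n")
  cat(sprintf("  distance  %.0f mm total (center %.0f / periphery %.0f)\n",
              x$total_distance_mm, x$distance_center_mm, x$distance_periphery_mm))
  cat(sprintf("  speed     mean %.1f, max %.1f mm/s\n",
              x$mean_speed_mm_s, x$max_speed_mm_s))
  cat(sprintf("  time      center %.1f s / periphery %.1f s of %.1f s; immobile %.1f s\n",
              x$time_center_s, x$time_periphery_s, x$duration_s,
              x$immobility_time_s))
  invisible(x)
}
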