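test_that("velocity matches closed forms", {
  calib <- unit_calib()
  # 2 px/frame at 30 fps, 1 mm/px -> 60 mm/s
  tr <- straight_track(40, dx = 2)
  expect_equal(velocity(tr, calib, smooth_s = 0), rep(60, 40), tolerance = 1e-10)
  # stationary
  expect_true(all(velocity(straight_track(60), calib) == 0))
  # smoothing reduces apparent speed of a jittering stationary track
  set.seed(1)
  nz <- straight_track(120)
  nz$x_px <- nz$x_px + rnorm(120)
  nz$y_px <- nz$y_px + rnorm(120)
  expect_lt(mean(velocity(nz, calib, smooth_s = 0.5)),
            mean(velocity(nz, calib, smooth_s = 0)))
  expect_error(velocity(straight_track(2), calib), "3 frames")
})

test_that("occupancy maps conserve time", {
  calib <- unit_calib()
  # stationary 10 s -> one cell holds all of it
  hm <- occupancy_heatmap(straight_track(300), calib, 10)
  expect_equal(max(hm), 10)
  expect_equal(sum(hm > 0), 1L)
  expect_equal(sum(hm), 10)
  # uniform sweep across one row: 8 cells get ~duration/8 each
  sw <- straight_track(320)
  sw$x_px <- seq(0, 79.9, length.out = 320)
  sw$y_px <- rep(50, 320)
  hm2 <- occupancy_heatmap(sw, calib, 10)
  row_cells <- hm2[6, 1:8]
  expect_equal(unname(row_cells), rep(320 / 30 / 8, 8), tolerance = 0.05)
  # conservation for an arbitrary (clipped) random walk
  set.seed(2)
  rw <- straight_track(500)
  rw$x_px <- cumsum(rnorm(500, 0, 3)) + 50
  rw$y_px <- cumsum(rnorm(500, 0, 3)) + 50
  expect_warning(hm3 <- occupancy_heatmap(rw, calib, 32), "clipped")
  expect_equal(sum(hm3), 500 / 30)
  expect_error(occupancy_heatmap(rw, calib, 1), "grid_n")
})

test_that("log heat map is the order-preserving log1p", {
  m <- matrix(c(0, exp(1) - 1, 2, 0.5), 2)
  lm_ <- log_heatmap(structure(m, class = c("occupancy_map", "matrix"),
                               cell_mm = c(1, 1), duration_s = sum(m)))
  expect_equal(unclass(lm_)[1, 1], 0)
  expect_equal(unclass(lm_)[2, 1], 1)
  expect_true(all(order(as.numeric(m)) == order(as.numeric(unclass(lm_)))))
})

test_that("zone metrics follow arena geometry", {
  calib <- unit_calib()
  # track that never leaves the center zone
  ctr <- straight_track(90, x0 = 45, y0 = 45, dx = 0.1)
  zm <- zone_metrics(ctr, calib)
  expect_equal(zm$time_periphery_s, 0)
  expect_equal(zm$distance_periphery_mm, 0)
  expect_equal(zm$time_center_s + zm$time_periphery_s, zm$duration_s)
  # square path along the walls: distance ~ perimeter, no center time
  side <- seq(5, 95, length.out = 100)
  sq <- data.frame(
    x_px = c(side, rep(95, 100), rev(side), rep(5, 100)),
    y_px = c(rep(5, 100), side, rep(95, 100), rev(side)))
  sq$frame <- seq_len(nrow(sq)); sq$time_s <- (sq$frame - 1) / 30
  zs <- zone_metrics(sq, calib)
  expect_equal(zs$total_distance_mm, 4 * 90, tolerance = 0.02)
  expect_equal(zs$time_center_s, 0)
  # stationary track: fully immobile
  zi <- zone_metrics(straight_track(900), calib)
  expect_equal(zi$immobility_time_s, 30)
  # fast mover: no immobility
  zf <- zone_metrics(straight_track(300, dx = 0.25), calib)
  expect_equal(zf$immobility_time_s, 0)
})

test_that("distance is reversal-invariant and zone times rotation-invariant", {
  calib <- unit_calib()
  set.seed(3)
  rw <- straight_track(400)
  rw$x_px <- 50 + cumsum(rnorm(400, 0, 1.5)) %% 40
  rw$y_px <- 50 + cumsum(rnorm(400, 0, 1.5)) %% 40
  zm <- zone_metrics(rw, calib)
  rev_ <- rw
  rev_$x_px <- rev(rw$x_px); rev_$y_px <- rev(rw$y_px)
  expect_equal(zone_metrics(rev_, calib)$total_distance_mm, zm$total_distance_mm)
  rot <- rw
  rot$x_px <- rw$y_px; rot$y_px <- 100 - rw$x_px  # 90 deg in a square arena
  zr <- zone_metrics(rot, calib)
  expect_equal(zr$time_center_s, zm$time_center_s)
  expect_equal(zr$time_periphery_s, zm$time_periphery_s)
})

test_that("tracked metrics agree with truth-derived metrics on clean scenes", {
  sc <- tiny_oft_scene(duration_s = 8, seed = 5)
  trk <- track_video(sc$video, sc$roi, run_config("rat"))
  err <- sqrt((trk$x_px - sc$truth$x_px)^2 + (trk$y_px - sc$truth$y_px)^2)
  p95 <- unname(quantile(err, 0.95))
  truth_track <- data.frame(time_s = sc$truth$time_s, x_px = sc$truth$x_px,
                            y_px = sc$truth$y_px)
  zt <- zone_metrics(truth_track, sc$calib)
  zm <- zone_metrics(trk, sc$calib)
  # 2% when tracking error is within the 2 px premise; otherwise widen by
  # the per-frame jitter the tracker actually delivered
  tol <- 0.02 + max(p95, 2) * nrow(trk) * sc$calib$mm_per_px_x /
    zt$total_distance_mm
  expect_equal(zm$total_distance_mm, zt$total_distance_mm, tolerance = tol)
  expect_equal(zm$time_center_s + zm$time_periphery_s, zt$duration_s)
})
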