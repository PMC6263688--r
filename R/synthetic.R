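# smooth frozen random field: white noise blurred to ~`corr_px` correlation
# length, rescaled to unit sd then multiplied by `strength`
smooth_texture <- function(nr, nc, corr_px, strength) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  gx <- dnorm(seq(-3 * corr_px, 3 * corr_px), sd = corr_px)
  gx <- gx / sum(gx)
  pad <- function(v, n) c(v, rep(0, n - length(v)))
  kr <- fft(pad(gx, nr)); kc <- fft(pad(gx, nc))
  Z <- stats::mvfft(z)
  Z <- Z * matrix(kr, nr, nc)
  z <- Re(stats::mvfft(Z, inverse = TRUE)) / nr
  Z <- stats::mvfft(t(z))
  Z <- Z * matrix(kc, nc, nr)
  z <- t(Re(stats::mvfft(Z, inverse = TRUE)) / nc)
  z <- z - mean(z)
  z * (strength / sd(z))
}

# elliptic partial-volume coverage: 1 inside, 0 outside, linear ramp of
# `feather` px across the boundary
ellipse_coverage <- function(nr, nc, cx, cy, ax, ay, feather) {
  xs <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  ys <- matrix(rep(0:(nr - 1), nc), nr, nc)
  rho <- sqrt(((xs - cx) / ax)^2 + ((ys - cy) / ay)^2)
  if (feather > 0) pmin(1, pmax(0, 0.5 - (rho - 1) * min(ax, ay) / feather))
  else (rho <= 1) * 1
}

#' Breathing-scene configuration
#'
#' Describes a synthetic thermal scene of an anesthetized rodent in frontal
#' view: a warm, textured elliptic body on a cooler noisy background, with a
#' thorax sub-region that oscillates vertically at the commanded
#' breaths/min profile. Defaults emulate a 640 x 480 px, 60 fps acquisition;
#' pass smaller `width`/`height`/`fps` for scaled-down scenes (the body and
#' chest geometry scale with the frame).
#'
#' @param width,height frame size in px.
#' @param fps frame rate.
#' @param duration_s scene length in seconds.
#' @param background_c,body_c background and body temperature, degrees C.
#' @param noise_sigma_c per-pixel iid sensor noise sd, degrees C.
#' @param amplitude_px peak chest displacement in px (> 0; sub-pixel values
#'   are rendered by bilinear shifting and remain detectable).
#' @param rr_profile commanded rate: a single breaths/min value or a
#'   function of time (seconds) returning breaths/min.
#' @param texture_strength_c sd of the frozen body texture, degrees C (> 0:
#'   corner detection needs gradients a flat blob lacks).
#' @param texture_corr_px texture correlation length in px.
#' @param feather_px partial-volume softening width of the body edge in px
#'   (emulates optics blur; 0 gives a hard edge).
#' @param halo_scale axis scale of the warm periphery (fur fringe, limbs,
#'   tail base) surrounding the core body; values `<= 1` disable it. The
#'   periphery sits at an intermediate temperature, giving thermograms
#'   their characteristic background / periphery / core class structure.
#' @param halo_c periphery temperature, degrees C; default 35% of the
#'   background-to-body contrast above background.
#' @param species optional species preset; when given, the commanded rates
#'   must lie inside the species passband.
#' @param seed RNG seed; the same seed yields a bit-identical scene.
#' @return An object of class `breath_scene_config`.
#' @export
breath_scene_config <- function(width = 640, height = 480, fps = 60,
                                duration_s = 60,
                                background_c = 22, body_c = 35,
                                noise_sigma_c = 0.3, amplitude_px = 1.5,
                                rr_profile = 54, texture_strength_c = 1.5,
                                texture_corr_px = 3, feather_px = 1.5,
                                halo_scale = 1.35, halo_c = NULL,
                                species = NULL, seed = 1L) {
  if (amplitude_px <= 0) stop("`amplitude_px` must be positive")
  if (texture_strength_c <= 0) stop("`texture_strength_c` must be positive")
  rr_fun <- if (is.function(rr_profile)) rr_profile else function(t) rep(rr_profile, length(t))
  tt <- seq(0, duration_s, by = 1 / fps)
  rr <- rr_fun(tt)
  if (any(rr <= 0) || any(rr >= 60 * fps / 2))
    stop("commanded rates must lie in (0, 60 * fps / 2) breaths/min")
  if (!is.null(species)) {
    band <- 60 * species_passband(species)
    if (any(rr < band[1]) || any(rr > band[2]))
      stop("commanded rates leave the ", species, " passband [",
           band[1], ", ", band[2], "] breaths/min")
  }
  if (is.null(halo_c)) halo_c <- background_c + 0.35 * (body_c - background_c)
  cx <- 0.50 * width; cy <- 0.55 * height
  ax <- 0.22 * width; ay <- 0.20 * height
  chest_w <- 2L * floor(0.55 * ax); chest_h <- max(8L, floor(0.5 * ay))
  chest_x0 <- as.integer(round(cx - chest_w / 2))
  chest_y0 <- as.integer(round(cy - 0.55 * ay))
  structure(list(width = as.integer(width), height = as.integer(height),
                 fps = fps, duration_s = duration_s,
                 background_c = background_c, body_c = body_c,
                 noise_sigma_c = noise_sigma_c, amplitude_px = amplitude_px,
                 rr_fun = rr_fun, texture_strength_c = texture_strength_c,
                 texture_corr_px = texture_corr_px, feather_px = feather_px,
                 halo_scale = halo_scale, halo_c = halo_c,
                 cx = cx, cy = cy, ax = ax, ay = ay,
                 chest = c(x0 = chest_x0, y0 = chest_y0,
                           w = as.integer(chest_w), h = as.integer(chest_h)),
                 species = species, seed = as.integer(seed)),
            class = "breath_scene_config")
}

#' Thorax ROI of a breathing scene
#'
#' The chest sub-region expanded by a small margin — the rectangle a user
#' would draw around the thorax.
#'
#' @param cfg a [breath_scene_config()].
#' @param margin_px margin around the chest rectangle.
#' @return A [rect_roi()].
#' @export
breath_roi <- function(cfg, margin_px = 4L) {
  ch <- cfg$chest
  rect_roi(ch["x0"] - margin_px, ch["y0"] - margin_px,
           ch["x0"] + ch["w"] + margin_px, ch["y0"] + ch["h"] + margin_px)
}

#' True body mask of a synthetic scene
#'
#' The commanded elliptic body extent (coverage >= 0.5, i.e. the exact
#' ellipse regardless of edge feathering).
#'
#' @param cfg a [breath_scene_config()].
#' @return Logical matrix (height x width).
#' @export
scene_body_mask <- function(cfg) {
  ellipse_coverage(cfg$height, cfg$width, cfg$cx, cfg$cy, cfg$ax, cfg$ay, 0) > 0
}

#' Render a synthetic breathing scene
#'
#' Builds the static scene (noisy background, feathered textured body),
#' displaces the chest sub-region vertically by
#' `amplitude * sin(2 pi integral of f(t) dt)` with bilinear sub-pixel
#' shifting, and adds per-frame iid Gaussian sensor noise. The commanded
#' rate profile sampled every `truth_hop_s` is returned as ground truth.
#'
#' @param cfg a [breath_scene_config()].
#' @param truth_hop_s sampling interval of the truth trace in seconds.
#' @return List with `video` (a [thermal_video()]), `truth` (data frame
#'   `time_s`, `rr_bpm`), `roi` (thorax [rect_roi()]) and `config`.
#' @export
make_breathing_video <- function(cfg, truth_hop_s = 1) {
  stopifnot(inherits(cfg, "breath_scene_config"))
  nr <- cfg$height; nc <- cfg$width
  nf <- as.integer(round(cfg$duration_s * cfg$fps))
  if (nf < 2L) stop("scene must span at least 2 frames")
  ch <- cfg$chest
  margin <- as.integer(ceiling(cfg$amplitude_px) + 2L)
  if (ch["y0"] - margin < 0 || ch["y0"] + ch["h"] + margin > nr)
    stop("infeasible geometry: chest rectangle plus margin leaves the frame")
  set.seed(cfg$seed)
  tex <- smooth_texture(nr, nc, cfg$texture_corr_px, cfg$texture_strength_c)
  A <- cfg$body_c + tex
  s <- ellipse_coverage(nr, nc, cfg$cx, cfg$cy, cfg$ax, cfg$ay, cfg$feather_px)
  S <- matrix(cfg$background_c, nr, nc)
  if (cfg$halo_scale > 1) {  # warm periphery between background and core
    sh <- ellipse_coverage(nr, nc, cfg$cx, cfg$cy,
                           cfg$halo_scale * cfg$ax, cfg$halo_scale * cfg$ay,
                           2 * max(cfg$feather_px, 1))
    S <- S + (cfg$halo_c - cfg$background_c) * sh
  }
  S <- S + (A - S) * s
  P <- A[(ch["y0"] - margin + 1L):(ch["y0"] + ch["h"] + margin),
         (ch["x0"] + 1L):(ch["x0"] + ch["w"]), drop = FALSE]
  tt <- (seq_len(nf) - 1) / cfg$fps
  f_hz <- cfg$rr_fun(tt) / 60
  phase <- 2 * pi * cumsum(f_hz) / cfg$fps
  d <- cfg$amplitude_px * sin(phase)
  frames <- cpp_render_breathing(S, P, ch["x0"], ch["y0"], ch["w"], ch["h"],
                                 margin, d, cfg$noise_sigma_c)
  truth_t <- seq(truth_hop_s, nf / cfg$fps, by = truth_hop_s)
  list(video = thermal_video(frames, cfg$fps, "radiometric_celsius"),
       truth = data.frame(time_s = truth_t, rr_bpm = cfg$rr_fun(truth_t)),
       roi = breath_roi(cfg), config = cfg)
}

#' Open-field-scene configuration
#'
#' A warm textured body performing a bounded correlated random walk in a
#' rectangular arena viewed from above. `thigmotaxis_bias` in `[0, 1]`
#' steers the walk's heading toward the nearest wall, emulating the
#' wall-hugging of anxious animals.
#'
#' @param width,height frame size in px.
#' @param fps frame rate.
#' @param duration_s scene length in seconds.
#' @param arena_px arena rectangle in the frame ([rect_roi()]); defaults to
#'   the frame minus a 4-px border.
#' @param arena_mm physical arena size `c(w, h)` in mm.
#' @param body_ax_px,body_ay_px body ellipse semi-axes in px.
#' @param speed_mm_s mean walking speed of the correlated random walk.
#' @param turn_sd_rad heading diffusion, radians per sqrt(second).
#' @param thigmotaxis_bias wall-attraction strength in `[0, 1]`.
#' @param background_c,body_c,noise_sigma_c,texture_strength_c,texture_corr_px,feather_px
#'   rendering parameters as in [breath_scene_config()].
#' @param seed RNG seed.
#' @return An object of class `oft_scene_config`.
#' @export
oft_scene_config <- function(width = 160, height = 120, fps = 30,
                             duration_s = 30, arena_px = NULL,
                             arena_mm = c(720, 720),
                             body_ax_px = 24, body_ay_px = 15,
                             speed_mm_s = 120, turn_sd_rad = 1.5,
                             thigmotaxis_bias = 0,
                             background_c = 22, body_c = 35,
                             noise_sigma_c = 0.3, texture_strength_c = 1.5,
                             texture_corr_px = 3, feather_px = 1.5,
                             halo_scale = 1.35, halo_c = NULL,
                             seed = 1L) {
  if (is.null(arena_px)) arena_px <- rect_roi(4, 4, width - 4, height - 4)
  stopifnot(inherits(arena_px, "rect_roi"))
  if (thigmotaxis_bias < 0 || thigmotaxis_bias > 1)
    stop("`thigmotaxis_bias` must be in [0, 1]")
  if (2 * body_ax_px >= arena_px$x1 - arena_px$x0 ||
      2 * body_ay_px >= arena_px$y1 - arena_px$y0)
    stop("body does not fit the arena")
  if (is.null(halo_c)) halo_c <- background_c + 0.35 * (body_c - background_c)
  structure(list(width = as.integer(width), height = as.integer(height),
                 fps = fps, duration_s = duration_s, arena_px = arena_px,
                 arena_mm = arena_mm, body_ax_px = body_ax_px,
                 body_ay_px = body_ay_px, speed_mm_s = speed_mm_s,
                 turn_sd_rad = turn_sd_rad,
                 thigmotaxis_bias = thigmotaxis_bias,
                 background_c = background_c, body_c = body_c,
                 noise_sigma_c = noise_sigma_c,
                 texture_strength_c = texture_strength_c,
                 texture_corr_px = texture_corr_px, feather_px = feather_px,
                 halo_scale = halo_scale, halo_c = halo_c,
                 seed = as.integer(seed)),
            class = "oft_scene_config")
}

#' Render a synthetic open-field scene
#'
#' The body center follows a correlated random walk (Ornstein-Uhlenbeck
#' speed around `speed_mm_s`, diffusing heading, optional wall attraction)
#' reflected at the walls so the body always stays inside the arena. The
#' per-frame center in px and mm is returned as ground truth.
#'
#' @param cfg an [oft_scene_config()].
#' @return List with `video` (a [thermal_video()]), `truth` (data frame
#'   `frame`, `time_s`, `x_px`, `y_px`, `x_mm`, `y_mm`), `roi` (body
#'   [rect_roi()] in the first frame), `calib` (the matching
#'   [arena_calibration()]) and `config`.
#' @export
make_oft_video <- function(cfg) {
  stopifnot(inherits(cfg, "oft_scene_config"))
  nf <- as.integer(round(cfg$duration_s * cfg$fps))
  if (nf < 2L) stop("scene must span at least 2 frames")
  set.seed(cfg$seed)
  ap <- cfg$arena_px
  mmx <- cfg$arena_mm[1] / (ap$x1 - ap$x0)
  mmy <- cfg$arena_mm[2] / (ap$y1 - ap$y0)
  # walk bounds in px: body (plus periphery and feather) stays in the arena
  hs <- max(1, cfg$halo_scale)
  pad_x <- cfg$body_ax_px * hs + 2 * cfg$feather_px
  pad_y <- cfg$body_ay_px * hs + 2 * cfg$feather_px
  lo_x <- ap$x0 + pad_x; hi_x <- ap$x1 - 1 - pad_x
  lo_y <- ap$y0 + pad_y; hi_y <- ap$y1 - 1 - pad_y
  dt <- 1 / cfg$fps
  theta <- runif(1, 0, 2 * pi)
  v <- cfg$speed_mm_s
  x <- runif(1, lo_x, hi_x); y <- runif(1, lo_y, hi_y)
  xs <- numeric(nf); ys <- numeric(nf)
  reflect <- function(p, lo, hi) {
    while (p < lo || p > hi) p <- if (p < lo) 2 * lo - p else 2 * hi - p
    p
  }
  for (t in seq_len(nf)) {
    xs[t] <- x; ys[t] <- y
    theta <- theta + cfg$turn_sd_rad * sqrt(dt) * rnorm(1)
    if (cfg$thigmotaxis_bias > 0) {
      # steer toward the nearest wall point
      dw <- c(x - lo_x, hi_x - x, y - lo_y, hi_y - y)
      wall_dir <- switch(which.min(dw), pi, 0, -pi / 2, pi / 2)
      dth <- atan2(sin(wall_dir - theta), cos(wall_dir - theta))
      theta <- theta + 0.08 * cfg$thigmotaxis_bias * dth
    }
    v <- v + 0.1 * (cfg$speed_mm_s - v) + 0.2 * cfg$speed_mm_s * sqrt(dt) * rnorm(1)
    v <- max(0, v)
    x <- x + v * dt * cos(theta) / mmx
    y <- y + v * dt * sin(theta) / mmy
    if (x < lo_x || x > hi_x) { x <- reflect(x, lo_x, hi_x); theta <- pi - theta }
    if (y < lo_y || y > hi_y) { y <- reflect(y, lo_y, hi_y); theta <- -theta }
  }
  # body appearance patch in body-frame coordinates
  th <- 2L * as.integer(ceiling(cfg$body_ay_px + cfg$feather_px)) + 5L
  tw <- 2L * as.integer(ceiling(cfg$body_ax_px + cfg$feather_px)) + 5L
  TEX <- cfg$body_c + smooth_texture(th, tw, cfg$texture_corr_px,
                                     cfg$texture_strength_c)
  frames <- cpp_render_oft(cfg$height, cfg$width, xs, ys,
                           cfg$body_ax_px, cfg$body_ay_px, cfg$feather_px,
                           TEX, cfg$background_c, cfg$noise_sigma_c,
                           cfg$halo_scale, cfg$halo_c)
  truth <- data.frame(frame = seq_len(nf), time_s = (seq_len(nf) - 1) * dt,
                      x_px = xs, y_px = ys,
                      x_mm = (xs - ap$x0) * mmx, y_mm = (ys - ap$y0) * mmy)
  roi <- rect_roi(floor(xs[1] - cfg$body_ax_px), floor(ys[1] - cfg$body_ay_px),
                  ceiling(xs[1] + cfg$body_ax_px) + 1,
                  ceiling(ys[1] + cfg$body_ay_px) + 1)
  list(video = thermal_video(frames, cfg$fps, "radiometric_celsius"),
       truth = truth, roi = roi,
       calib = arena_calibration(cfg$arena_mm[1], cfg$arena_mm[2], ap),
       config = cfg)
}
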