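test_that("tracker initialization builds a normalized template library", {
  fr <- matrix(as.integer(pmin(255, pmax(0, 128 +
    60 * thermowelfare:::smooth_texture(60, 80, 3, 1)))), 60, 80)
  cfg <- run_config("rat")
  st <- init_tracker(fr, rect_roi(30, 20, 50, 40), cfg, seed = 5)
  expect_equal(ncol(st$templates), 10)
  norms <- sqrt(colSums(st$templates^2))
  expect_true(all(abs(norms - 1) < 1e-6))
  expect_lt(max(abs(colMeans(st$templates))), 1e-9)
  expect_true(all(abs(sum(st$weights) - 1) < 1e-12))
  # determinism: same seed twice -> bit-identical particles
  st2 <- init_tracker(fr, rect_roi(30, 20, 50, 40), cfg, seed = 5)
  expect_identical(st$particles, st2$particles)
  # too-small patch
  expect_error(init_tracker(fr, rect_roi(0, 0, 4, 4), cfg), "64 px")
  # zero-variance patch
  expect_error(init_tracker(matrix(7L, 60, 80), rect_roi(30, 20, 50, 40), cfg),
               "zero-variance")
})

test_that("state transitions perturb particles as configured", {
  fr <- matrix(as.integer(pmin(255, pmax(0, 128 +
    60 * thermowelfare:::smooth_texture(60, 80, 3, 1)))), 60, 80)
  cfg <- run_config("rat", tracker = list(n_particles = 10000L, sigma_xy = 2))
  st <- init_tracker(fr, rect_roi(30, 20, 50, 40), cfg, seed = 1)
  cand <- propagate(st)
  expect_equal(nrow(cand), 10000)
  # empirical std of the x-jump ~ sigma_xy within 10%
  expect_equal(sd(cand[, 1] - st$particles[, 1]), 2, tolerance = 0.1)
  # degenerate noise: candidates identical to parents
  cfg0 <- run_config("rat", tracker = list(sigma_xy = 0, sigma_scale = 0))
  st0 <- init_tracker(fr, rect_roi(30, 20, 50, 40), cfg0, seed = 1)
  expect_equal(propagate(st0), st0$particles, ignore_attr = TRUE)
})

test_that("sparse reconstruction is exact on members and honest off-span", {
  set.seed(11)
  d <- 64; m <- 5
  T <- vapply(seq_len(m), function(i) {
    v <- rnorm(d); v <- v - mean(v); v / sqrt(sum(v^2))
  }, numeric(d))
  r1 <- sparse_reconstruct(T[, 1], T)
  expect_lte(r1$error, 1e-4)
  expect_gt(r1$coef[1], 0.9 * sum(r1$coef))
  # y orthogonal to all templates: trivial templates absorb it
  y <- rnorm(d); y <- y - mean(y)
  y <- y - T %*% solve(crossprod(T), crossprod(T, y))
  y <- as.numeric(y) / sqrt(sum(y^2))
  r2 <- sparse_reconstruct(y, T)
  expect_equal(r2$error, 1, tolerance = 0.05)          # ||y||^2 = 1
  expect_lt(sum(r2$coef), 0.05)
  expect_gt(sum(abs(r2$trivial)), 0.5)
})

test_that("the l1 solver matches an independent convex solver", {
  set.seed(12)
  for (i in 1:4) {
    d <- 9; m <- 3
    T <- vapply(seq_len(m), function(j) {
      v <- rnorm(d); v / sqrt(sum(v^2))
    }, numeric(d))
    y <- rnorm(d); y <- y / sqrt(sum(y^2))
    lam <- 0.01
    r <- sparse_reconstruct(y, T, lam, tol = 1e-9, maxit = 5000)
    D <- cbind(T, diag(d), -diag(d))
    g <- glmnet::glmnet(D, y, lambda = lam / (2 * d), lower.limits = 0,
                        intercept = FALSE, standardize = FALSE, thresh = 1e-14)
    b <- as.numeric(coef(g))[-1]
    obj_glmnet <- sum((y - D %*% b)^2) + lam * sum(abs(b))
    obj_ours <- l1_objective(y, T, r$coef, r$trivial, lam)
    expect_equal(r$objective, obj_ours, tolerance = 1e-10)
    expect_lt(abs(obj_ours - obj_glmnet), 1e-3)
    # KKT: correlations bounded by lambda, tight on the active set
    grad <- 2 * as.numeric(crossprod(D, y - T %*% r$coef - r$trivial))
    expect_lt(max(grad) - lam, 1e-6)
  }
})

test_that("reconstruction error is non-negative and zero only in-span", {
  set.seed(13)
  d <- 36; m <- 4
  T <- vapply(seq_len(m), function(j) {
    v <- rnorm(d); v <- v - mean(v); v / sqrt(sum(v^2))
  }, numeric(d))
  for (i in 1:5) {
    w <- runif(m)
    y <- as.numeric(T %*% w)
    r <- sparse_reconstruct(y / sqrt(sum(y^2)), T, lambda = 1e-4)
    expect_gte(r$error, 0)
    expect_lt(r$error, 1e-4)  # non-negative combination reconstructs
  }
})

test_that("a static scene is tracked without drift and deterministically", {
  set.seed(14)
  # a close-up body: argmin jitter inside the one-pixel template basin is
  # ~1 px regardless of scale, so path length is judged at a realistic
  # body size
  sc <- tiny_oft_scene(duration_s = 3, speed_mm_s = 0, seed = 3,
                       body_ax_px = 30, body_ay_px = 19)
  cfg <- run_config("rat", rng_seed = 21L)
  trk1 <- track_video(sc$video, sc$roi, cfg)
  trk2 <- track_video(sc$video, sc$roi, cfg)
  expect_identical(trk1$x_px, trk2$x_px)   # fixed seed, bit-identical
  expect_identical(trk1$error, trk2$error)
  drift <- sqrt((trk1$x_px - trk1$x_px[1])^2 + (trk1$y_px - trk1$y_px[1])^2)
  expect_lt(max(drift), 3)
  # stationary animal: path length below 2% of body length x frames
  seg <- sum(sqrt(diff(trk1$x_px)^2 + diff(trk1$y_px)^2))
  expect_lt(seg, 0.02 * 2 * sc$config$body_ax_px * nrow(trk1))
})

test_that("an impossible jump is flagged as low confidence", {
  set.seed(15)
  cfg_s <- oft_scene_config(duration_s = 3, speed_mm_s = 0, seed = 6)
  sc <- make_oft_video(cfg_s)
  fr <- sc$video$frames
  nf <- dim(fr)[3]
  half <- floor(nf / 2)
  # teleport: second half shows the body 50 px away (shifted scene)
  shifted <- fr[, c(51:dim(fr)[2], rep(dim(fr)[2], 50)), , drop = FALSE]
  fr[, , (half + 1):nf] <- shifted[, , (half + 1):nf]
  v <- thermal_video(fr, 30, "radiometric_celsius")
  trk <- track_video(v, sc$roi, run_config("rat"))
  expect_gt(trk$error[half + 1], 3 * median(trk$error[2:half]))
  expect_true(any(trk$low_confidence[(half + 1):min(half + 5, nf)]))
})

test_that("template updating adapts to appearance change", {
  fr <- matrix(as.integer(pmin(255, pmax(0, 128 +
    60 * thermowelfare:::smooth_texture(60, 80, 3, 1)))), 60, 80)
  cfg <- run_config("rat")
  st <- init_tracker(fr, rect_roi(30, 20, 50, 40), cfg, seed = 2)
  # result equal to an existing template: importance grows, no replacement
  tpl <- st$templates
  st2 <- update_templates(st, st$templates[, 3])
  expect_equal(ncol(st2$templates), ncol(tpl))
  expect_true(all(st2$templates == tpl))
  expect_gt(st2$template_importance[3], st$template_importance[3])
  # orthogonal result: lowest-importance template replaced
  set.seed(16)
  q <- rnorm(nrow(tpl)); q <- q - mean(q)
  q <- q - tpl %*% crossprod(tpl, q)  # orthogonalize approximately
  q <- normalize_patch(as.numeric(q))
  worst <- which.min(st2$template_importance)
  st3 <- update_templates(st2, q)
  expect_equal(st3$templates[, worst], q)
})

test_that("tracking follows a moving synthetic animal", {
  sc <- tiny_oft_scene(duration_s = 8, seed = 4)
  trk <- track_video(sc$video, sc$roi, run_config("rat"))
  err <- sqrt((trk$x_px - sc$truth$x_px)^2 + (trk$y_px - sc$truth$y_px)^2)
  expect_lte(quantile(err, 0.95), 5)
  expect_lt(max(err), sc$config$body_ax_px)  # never loses the target
  # tracker centroid vs intensity-weighted centroid of the segmented mask
  cd <- vapply(seq(1, nrow(trk), by = 5), function(i) {
    f <- sc$video$frames[, , i]
    seg <- segment_animal(f, multilevel_otsu(f, 3))
    w <- (f - min(f)) * seg$mask
    cx <- sum(col(f) * w) / sum(w) - 1
    cy <- sum(row(f) * w) / sum(w) - 1
    sqrt((trk$x_px[i] - cx)^2 + (trk$y_px[i] - cy)^2)
  }, 0)
  expect_lte(median(cd), 3)
})
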