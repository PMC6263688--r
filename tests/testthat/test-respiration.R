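mk_traj <- function(x, y) {
  structure(list(x = x, y = y,
                 valid = matrix(TRUE, nrow(x), ncol(x)), t0_frame = 0L),
            class = "trajectory_matrix")
}

test_that("pruning keeps exactly the stable quantile with deterministic ties", {
  set.seed(1)
  # 100 points, 25% pruned -> 75 remain
  x <- matrix(rnorm(50 * 100, sd = 0.1), 50, 100)
  y <- matrix(rnorm(50 * 100, sd = 0.1), 50, 100)
  pr <- prune_unstable(mk_traj(x, y), 25)
  expect_equal(ncol(pr$x), 75)
  # identical trajectories: ties broken by point index, exactly ceil(.75 n)
  x2 <- matrix(rep(sin(1:40), 10), 40, 10)
  pr2 <- prune_unstable(mk_traj(x2, x2), 25)
  expect_equal(pr2$point_index, 1:8)  # ceiling(0.75 * 10) lowest indices
  # property: exact survivor count across n and percentiles
  for (n in c(9, 17, 40)) for (p in c(10, 25, 50)) {
    xr <- matrix(rnorm(20 * n), 20, n)
    expect_equal(ncol(prune_unstable(mk_traj(xr, xr), p)$x),
                 ceiling((1 - p / 100) * n))
  }
  expect_error(prune_unstable(mk_traj(x[, 1:3], y[, 1:3])), "at least 4")
})

test_that("pruning removes erratic trajectories", {
  set.seed(2)
  smooth <- matrix(rnorm(60 * 10, sd = 0.05), 60, 10)
  erratic <- matrix(sample(c(-20, 20), 60 * 2, TRUE) * runif(120), 60, 2)
  tr <- mk_traj(cbind(smooth, erratic), cbind(smooth, erratic) * 0)
  pr <- prune_unstable(tr, 25)
  expect_false(any(c(11, 12) %in% pr$point_index))
})

test_that("axis selection follows the dominant variance with a y tie-break", {
  t <- seq(0, 5, by = 1 / 30)
  osc <- outer(sin(2 * pi * t), rep(1, 6))
  flat <- matrix(0, length(t), 6)
  expect_identical(attr(select_axis(mk_traj(flat, osc)), "axis"), "y")
  expect_identical(attr(select_axis(mk_traj(osc, flat)), "axis"), "x")
  expect_identical(attr(select_axis(mk_traj(osc, osc)), "axis"), "y")
  out <- select_axis(mk_traj(flat, osc))
  expect_lt(max(abs(colMeans(out))), 1e-12)
})

test_that("band-pass design meets passband and stopband specs", {
  for (sp in c("rat", "mouse")) {
    band <- species_passband(sp)
    filt <- design_bandpass(band, 60)
    gain <- function(f) abs(sum(filt$coef *
      exp(-2i * pi * f / 60 * (seq_along(filt$coef) - 1))))
    mid <- if (sp == "rat") 1.5 else 2
    expect_lt(abs(20 * log10(gain(mid))), 1)            # within 1 dB of unity
    expect_lt(20 * log10(gain(band[1] - 0.4)), -40)     # stopband
    expect_lt(20 * log10(gain(band[2] + 0.4)), -40)
  }
  expect_error(design_bandpass(c(1, 40), 60), "below fs/2")
  expect_error(design_bandpass(c(0.1, 3), 60), "positive")
})

test_that("zero-phase filtering preserves in-band tones and kills out-of-band", {
  fs <- 30
  filt <- design_bandpass(c(0.6, 3.3), fs)
  t <- seq(1 / fs, 120, by = 1 / fs)
  # DC is deep in the stopband
  dc <- apply_filter(rep(3, length(t)), filt)
  expect_lt(max(abs(dc[300:3300])), 3e-3 * 3)
  # in-band 1.5 Hz tone: amplitude within 5%, no phase shift
  x <- sin(2 * pi * 1.5 * t)
  y <- apply_filter(x, filt)
  core <- 1000:2600
  fit <- lm(y[core] ~ sin(2 * pi * 1.5 * t[core]) + cos(2 * pi * 1.5 * t[core]))
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  phase <- atan2(coef(fit)[3], coef(fit)[2]) / (2 * pi)
  expect_equal(amp, 1, tolerance = 0.05)
  expect_lt(abs(phase), 0.01)
  # out-of-band 10 Hz attenuated >= 40 dB
  z <- apply_filter(sin(2 * pi * 10 * t), filt)
  expect_lt(max(abs(z[core])), 10^(-40 / 20))
  expect_error(apply_filter(x[1:100], filt), "too short")
})

test_that("PCA separates sources and respects rank", {
  set.seed(3)
  t <- seq(0, 10, by = 1 / 30)
  s1 <- sin(2 * pi * t)
  # rank-1 data: one sinusoid across all columns plus tiny noise
  X <- outer(s1, runif(8, 0.5, 2)) + matrix(rnorm(length(t) * 8, sd = 1e-3),
                                            length(t), 8)
  cs <- pca_decompose(X, 6)
  expect_lte(length(cs$variances), 6)
  expect_gte(cs$variances[1] / sum(cs$variances), 0.99)
  expect_gte(abs(cor(cs$scores[, 1], s1)), 0.999)
  expect_true(all(diff(cs$variances) <= 1e-9))
  expect_lt(max(abs(colMeans(cs$scores))), 1e-9)
  # two orthogonal sinusoids split across columns are both recovered
  s2 <- sin(2 * pi * 2.3 * t + 1)
  X2 <- cbind(outer(s1, c(1, 0.8, 0.9)), outer(s2, c(1, 1.1)))
  cs2 <- pca_decompose(X2, 6)
  expect_gte(max(abs(cor(cs2$scores[, 1:2], s1))), 0.995)
  expect_gte(max(abs(cor(cs2$scores[, 1:2], s2))), 0.995)
  # rank cap: 3 columns give 3 components even with k = 6
  expect_equal(ncol(pca_decompose(X[, 1:3], 6)$scores), 3)
  expect_error(pca_decompose(X[, 1, drop = FALSE]), "2 signal columns")
  expect_error(pca_decompose(matrix(0, 50, 4)), "rank 0")
})

test_that("periodicity score separates periodic from aperiodic components", {
  fs <- 30; band <- c(0.6, 3.3)
  t <- seq(1 / fs, 60, by = 1 / fs)
  p <- periodicity_score(sin(2 * pi * t), fs, band)
  expect_equal(p$f0, 1, tolerance = 0.01)
  expect_gte(p$score, 0.9)
  # white noise: low score (median over 100 seeds)
  set.seed(4)
  ns <- replicate(100, periodicity_score(rnorm(10 * fs), fs, band)$score)
  expect_lt(median(ns), 0.2)
  # harmonic-rich wave scores above a noisy sine
  t10 <- seq(1 / fs, 10, by = 1 / fs)
  sq <- sin(2 * pi * t10) + 0.5 * sin(2 * pi * 2 * t10)
  noisy <- sin(2 * pi * t10) + rnorm(length(t10), 0, 1)
  expect_gt(periodicity_score(sq, fs, band)$score,
            periodicity_score(noisy, fs, band)$score)
  expect_error(periodicity_score(rep(0, 10 * fs), fs, band), "zero-power")
  expect_error(periodicity_score(rnorm(30), fs, band), "4 seconds")
})

test_that("spectral argmax matches a brute-force DFT oracle", {
  fs <- 30; band <- c(0.6, 3.3)
  set.seed(5)
  for (i in 1:5) {
    f_true <- runif(1, 0.8, 3)
    x <- sin(2 * pi * f_true * seq(1 / fs, 12, by = 1 / fs)) +
      rnorm(12 * fs, 0, 0.3)
    f0 <- periodicity_score(x, fs, band)$f0
    f_oracle <- oracle_spectral_argmax(x, fs, band)
    expect_lt(abs(f0 - f_oracle), 0.01)  # within one resolution bin
  }
})

test_that("window RR estimation picks the most periodic component", {
  fs <- 30; band <- c(0.6, 3.3)
  t <- seq(1 / fs, 10, by = 1 / fs)
  set.seed(6)
  comps <- cbind(sin(2 * pi * 0.9 * t), rnorm(length(t)))
  est <- estimate_rr_window(comps, fs, band)
  expect_equal(est$rr_bpm, 54, tolerance = 0.6 / 54)
  expect_equal(est$pc_index, 1L)
  # breathing only on the third component
  comps3 <- cbind(rnorm(length(t), sd = 1), rnorm(length(t), sd = 1),
                  5 * sin(2 * pi * 1.2 * t))
  est3 <- estimate_rr_window(comps3, fs, band)
  expect_equal(est3$pc_index, 3L)
  expect_equal(est3$rr_bpm, 72, tolerance = 0.01 * 72)
  # all-noise components: lowest-index max-score component, low score
  noise <- matrix(rnorm(length(t) * 3), ncol = 3)
  estn <- estimate_rr_window(noise, fs, band)
  expect_true(estn$pc_index %in% 1:3)
  expect_lt(estn$score, 0.3)
})

test_that("rr_trace recovers a constant commanded rate end to end", {
  sc <- tiny_breath_scene(rr = 54, duration_s = 40, seed = 7)
  tr <- rr_trace(sc$video, sc$roi, run_config("rat"))
  expect_s3_class(tr, "rr_trace")
  expect_true(all(diff(tr$time_s) > 0))
  ok <- tr$valid
  expect_gte(mean(ok), 0.9)
  expect_true(all(abs(tr$rr_bpm_median[ok] - 54) <= 1))
  band <- 60 * species_passband("rat")
  expect_true(all(tr$rr_bpm[ok] >= band[1] & tr$rr_bpm[ok] <= band[2]))
})

test_that("rr_trace follows a step change within a window plus the median lag", {
  sc <- make_breathing_video(breath_scene_config(
    width = 128, height = 96, fps = 30, duration_s = 60,
    rr_profile = function(t) ifelse(t < 30, 50, 60), species = "rat", seed = 8))
  tr <- rr_trace(sc$video, sc$roi, run_config("rat"))
  late <- tr$valid & tr$time_s >= 30 + 10 + 5
  expect_true(all(abs(tr$rr_bpm_median[late] - 60) <= 1))
  early <- tr$valid & tr$time_s <= 30
  expect_true(all(abs(tr$rr_bpm_median[early] - 50) <= 1))
})

test_that("the trailing median shrugs off a single corrupted window", {
  sc <- tiny_breath_scene(rr = 54, duration_s = 30, seed = 9)
  tr <- rr_trace(sc$video, sc$roi, run_config("rat"))
  med5 <- function(v, t, i)
    median(v[t > t[i] - 5 & t <= t[i]])
  bad <- tr$rr_bpm
  k <- which(tr$valid)[5]
  bad[k] <- bad[k] + 60
  for (i in which(tr$valid))
    expect_lt(abs(med5(bad, tr$time_s, i) - tr$rr_bpm_median[i]), 0.5)
})

test_that("agreement metrics match closed forms and a formula oracle", {
  ref <- data.frame(time_s = 1:20, rr_bpm = rep(50, 20))
  est <- data.frame(time_s = 1:20, rr_bpm = rep(50, 20))
  m <- evaluate_against_reference(est, ref)
  expect_equal(m$rmse_bpm, 0)
  expect_equal(m$mean_rel_err_pct, 0)
  expect_equal(m$p90_rel_err_pct, 0)
  expect_equal(m$bland_altman_bias_bpm, 0)
  # constant +1 offset on ref = 50
  est1 <- data.frame(time_s = 1:20, rr_bpm = rep(51, 20))
  m1 <- evaluate_against_reference(est1, ref)
  expect_equal(m1$rmse_bpm, 1)
  expect_equal(m1$mean_rel_err_pct, 2)
  expect_equal(m1$bland_altman_bias_bpm, 1)
  expect_equal(c(m1$loa_low_bpm, m1$loa_high_bpm), c(1, 1))
  # random pairs vs independent recomputation
  set.seed(10)
  r <- data.frame(time_s = 1:30, rr_bpm = runif(30, 40, 70))
  e <- data.frame(time_s = 1:30, rr_bpm = r$rr_bpm + rnorm(30))
  m2 <- evaluate_against_reference(e, r)
  o <- oracle_agreement(e$rr_bpm, r$rr_bpm)
  expect_equal(m2$rmse_bpm, o$rmse)
  expect_equal(m2$mean_rel_err_pct, o$eps)
  expect_equal(m2$p90_rel_err_pct, o$eps90)
  expect_equal(m2$pearson_r, o$r)
  expect_equal(c(m2$loa_low_bpm, m2$loa_high_bpm), o$loa)
  expect_gte(m2$p90_rel_err_pct, m2$mean_rel_err_pct)
  expect_error(evaluate_against_reference(e[1:2, ], r), "at least 3")
  expect_error(evaluate_against_reference(e, transform(r, rr_bpm = -rr_bpm)),
               "positive")
})
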