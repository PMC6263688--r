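test_that("two-population frames split exactly", {
  set.seed(1)
  fr <- matrix(sample(c(10, 200), 400, TRUE), 20, 20)
  th <- multilevel_otsu(fr, 2)
  expect_length(th, 1L)
  expect_gt(th, 10); expect_lt(th, 200)
  expect_identical(unname(fr > th), unname(fr == 200))

  fr3 <- matrix(rep(c(0, 120, 250), each = 100), 10, 30)
  th3 <- multilevel_otsu(fr3, 3)
  expect_length(th3, 2L)
  expect_true(th3[1] > 0 && th3[1] < 120)
  expect_true(th3[2] > 120 && th3[2] < 250)
})

test_that("multilevel Otsu equals the exhaustive-search oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    fr <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
    expect_equal(multilevel_otsu(fr, 3), oracle_otsu(fr, 3), tolerance = 1e-12)
    expect_equal(multilevel_otsu(fr, 2), oracle_otsu(fr, 2), tolerance = 1e-12)
  }
  # smooth bimodal frame as well
  set.seed(9)
  fr <- matrix(c(rnorm(400, 60, 10), rnorm(200, 180, 15)), 20, 30)
  expect_equal(multilevel_otsu(fr, 3), oracle_otsu(fr, 3), tolerance = 1e-12)
})

test_that("multilevel Otsu rejects degenerate frames", {
  expect_error(multilevel_otsu(matrix(5, 4, 4)), "constant")
  expect_error(multilevel_otsu(matrix(c(1, 2), 2, 2), 3), "distinct")
  expect_error(multilevel_otsu(matrix(1:9, 3), 5), "2, 3 or 4")
})

test_that("segmentation recovers the warm body on synthetic scenes", {
  sc <- tiny_breath_scene(duration_s = 2, seed = 3)
  fr <- sc$video$frames[, , 1]
  seg <- segment_animal(fr, multilevel_otsu(fr, 3))
  truth <- scene_body_mask(sc$config)
  expect_false(seg$empty)
  # mask covers >= 95% of the true ellipse ...
  expect_gte(sum(seg$mask & truth) / sum(truth), 0.95)
  # ... and stays within the ellipse dilated by 2 px
  pad <- truth
  for (s in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, 1), c(-1, -1),
                 c(1, -1), c(-1, 1), c(2, 0), c(-2, 0), c(0, 2), c(0, -2))) {
    sh <- truth
    sh <- sh[pmin(pmax(seq_len(nrow(sh)) + s[1], 1), nrow(sh)),
             pmin(pmax(seq_len(ncol(sh)) + s[2], 1), ncol(sh))]
    pad <- pad | sh
  }
  expect_true(all(!seg$mask | pad))
  # IoU invariant at default contrast/noise
  iou <- sum(seg$mask & truth) / sum(seg$mask | truth)
  expect_gte(iou, 0.9)
})

test_that("segmentation handles empty and inverted-contrast frames", {
  set.seed(4)
  fr <- matrix(rnorm(900, 22, 0.3), 30, 30)
  seg <- segment_animal(fr, c(30))  # threshold above all background
  expect_true(seg$empty)
  expect_equal(seg$n_foreground, 0L)
  # inverted contrast: the mask selects the (wrong) warmest region by design
  inv <- matrix(22, 30, 30); inv[10:20, 10:20] <- 10
  seg2 <- segment_animal(inv, multilevel_otsu(inv, 2))
  expect_true(all(which(seg2$mask) %in% which(inv == 22)))
  expect_error(segment_animal(fr, c(3, 2)), "increasing")
})

test_that("contrast stretch maps percentiles linearly to 0-255", {
  fr <- matrix(seq(20, 36, length.out = 256), 16, 16)
  out <- stretch_contrast(fr, 0, 100)
  expect_equal(out[fr == 20], 0)
  expect_equal(out[fr == 36], 255)
  expect_equal(out[which.min(abs(fr - 28))], 128, tolerance = 2)
  # identity on an already 0-255 ramp
  fr2 <- matrix(0:255, 16, 16)
  expect_true(all(abs(stretch_contrast(fr2, 0, 100) - fr2) <= 1))
})

test_that("percentile clipping saturates outliers and boosts interior contrast", {
  set.seed(5)
  fr <- matrix(rnorm(10000, 25, 2), 100, 100)
  hot <- sample(10000, 100)           # 1% hot outliers
  fr[hot] <- 80
  clipped <- stretch_contrast(fr, 1, 99)
  plain <- stretch_contrast(fr, 0, 100)
  expect_true(all(clipped[hot] == 255))
  interior <- setdiff(seq_len(10000), hot)
  expect_gt(diff(range(clipped[interior])), diff(range(plain[interior])))
})

test_that("contrast stretch is monotone and handles flat frames", {
  set.seed(6)
  fr <- matrix(rnorm(400, 0, 5), 20, 20)
  out <- stretch_contrast(fr, 5, 95)
  o <- order(fr)
  expect_true(all(diff(out[o]) >= 0))
  expect_warning(out0 <- stretch_contrast(matrix(7, 5, 5)), "contrast")
  expect_true(all(out0 == 0))
  expect_error(stretch_contrast(fr, 50, 40), "lo_pct")
})
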