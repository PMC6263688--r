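# Independent oracles, deliberately written with plain loops and direct
# formulas so they share no code path with the implementation.

# exhaustive-search multilevel Otsu over a 256-bin histogram (2 or 3 classes)
oracle_otsu <- function(frame, n_classes) {
  v <- as.numeric(frame)
  rng <- range(v)
  nb <- 256L
  bin <- pmin(nb, floor((v - rng[1]) / (rng[2] - rng[1]) * nb) + 1L)
  h <- tabulate(bin, nbins = nb) / length(v)
  mids <- seq_len(nb)
  bcv <- function(cuts) {
    bounds <- c(0L, cuts, nb)
    s <- 0
    for (k in seq_len(length(bounds) - 1L)) {
      sel <- (mids > bounds[k]) & (mids <= bounds[k + 1L])
      w <- sum(h[sel])
      if (w > 0) s <- s + w * (sum(h[sel] * mids[sel]) / w)^2
    }
    s
  }
  best <- NULL; best_v <- -Inf
  if (n_classes == 2L) {
    for (t1 in 1:(nb - 1L)) {
      v1 <- bcv(t1)
      if (v1 > best_v) { best_v <- v1; best <- t1 }
    }
  } else {
    for (t1 in 1:(nb - 2L)) for (t2 in (t1 + 1L):(nb - 1L)) {
      v1 <- bcv(c(t1, t2))
      if (v1 > best_v) { best_v <- v1; best <- c(t1, t2) }
    }
  }
  rng[1] + best * (rng[2] - rng[1]) / nb
}

# Shi-Tomasi min-eigenvalue response computed independently (Sobel gradients,
# 5x5 box structure tensor), plain loops
oracle_shi_tomasi <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  for (x in 2:(nc - 1)) for (y in 2:(nr - 1)) {
    gx[y, x] <- (img[y - 1, x + 1] + 2 * img[y, x + 1] + img[y + 1, x + 1] -
                 img[y - 1, x - 1] - 2 * img[y, x - 1] - img[y + 1, x - 1]) / 8
    gy[y, x] <- (img[y + 1, x - 1] + 2 * img[y + 1, x] + img[y + 1, x + 1] -
                 img[y - 1, x - 1] - 2 * img[y - 1, x] - img[y - 1, x + 1]) / 8
  }
  resp <- matrix(0, nr, nc)
  for (x in 4:(nc - 3)) for (y in 4:(nr - 3)) {
    w <- (-2):2
    ixx <- gx[y + w, x + w, drop = FALSE]
    sxx <- 0; sxy <- 0; syy <- 0
    for (dx in w) for (dy in w) {
      a <- gx[y + dy, x + dx]; b <- gy[y + dy, x + dx]
      sxx <- sxx + a * a; sxy <- sxy + a * b; syy <- syy + b * b
    }
    M <- matrix(c(sxx, sxy, sxy, syy), 2)
    resp[y, x] <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  }
  resp
}

# brute-force spectral argmax of a Hamming-windowed signal on a fine grid
oracle_spectral_argmax <- function(x, fs, band, grid_hz = 0.005) {
  n <- length(x)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  xw <- (x - mean(x)) * w
  fr <- seq(band[1], band[2], by = grid_hz)
  pw <- vapply(fr, function(f) {
    e <- exp(-2i * pi * f / fs * seq(0, n - 1))
    Mod(sum(xw * e))^2
  }, 0)
  fr[which.max(pw)]
}

# agreement metrics recomputed formula by formula
oracle_agreement <- function(est, ref) {
  d <- est - ref
  rel <- 100 * abs(d) / ref
  list(rmse = sqrt(sum(d^2) / length(d)),
       eps = sum(rel) / length(rel),
       eps90 = unname(quantile(rel, 0.9)),
       r = cor(est, ref),
       bias = sum(d) / length(d),
       loa = mean(d) + c(-1.96, 1.96) * sd(d))
}

# l1 objective of a coefficient vector on dictionary [T, I, -I]
l1_objective <- function(y, T, a, e, lambda) {
  sum((y - T %*% a - e)^2) + lambda * (sum(a) + sum(abs(e)))
}
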