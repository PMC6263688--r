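#' Multilevel Otsu thresholds
#'
#' Computes the `n_classes - 1` intensity cut points that maximize the
#' between-class variance of the frame's 256-bin histogram (binned over the
#' frame's min-max range), the discriminant-analysis criterion of Otsu
#' generalized to several classes. Thresholds are returned on the intensity
#' scale (upper edge of the last bin of each class), strictly increasing.
#'
#' @param frame numeric matrix.
#' @param n_classes number of intensity classes, 2-4.
#' @return Numeric vector of `n_classes - 1` thresholds.
#' @export
multilevel_otsu <- function(frame, n_classes = 3L) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L || n_classes > 4L) stop("`n_classes` must be 2, 3 or 4")
  v <- as.numeric(frame)
  rng <- range(v)
  if (!all(is.finite(rng))) stop("frame contains non-finite values")
  if (rng[1] == rng[2]) stop("constant frame: thresholds are undefined")
  nb <- 256L
  bin <- pmin(nb, floor((v - rng[1]) / (rng[2] - rng[1]) * nb) + 1L)
  h <- tabulate(bin, nbins = nb) / length(v)
  if (sum(h > 0) < n_classes) stop("frame needs at least `n_classes` distinct levels")
  # cumulative mass and first moment over bins
  cw <- cumsum(h)
  cm <- cumsum(h * seq_len(nb))
  # between-class variance of a class covering bins (a, b]:
  # w = cw[b]-cw[a], contribution w * mu^2 with mu = (cm[b]-cm[a])/w
  cls <- function(a, b) {  # a, b may be vectors of bin boundaries
    wa <- ifelse(a > 0L, cw[pmax(a, 1L)], 0)
    ma <- ifelse(a > 0L, cm[pmax(a, 1L)], 0)
    w <- cw[b] - wa
    m <- cm[b] - ma
    ifelse(w > 0, m * m / w, 0)
  }
  if (n_classes == 2L) {
    t1 <- seq_len(nb - 1L)
    crit <- cls(0L, t1) + cls(t1, nb)
    cut <- which.max(crit)
  } else if (n_classes == 3L) {
    t1 <- rep(seq_len(nb - 2L), times = (nb - 2L):1L)
    t2 <- unlist(lapply(seq_len(nb - 2L), function(i) (i + 1L):(nb - 1L)))
    crit <- cls(0L, t1) + cls(t1, t2) + cls(t2, nb)
    best <- which.max(crit)
    cut <- c(t1[best], t2[best])
  } else {
    combs <- utils::combn(nb - 1L, 3L)
    crit <- cls(0L, combs[1L, ]) + cls(combs[1L, ], combs[2L, ]) +
      cls(combs[2L, ], combs[3L, ]) + cls(combs[3L, ], nb)
    cut <- combs[, which.max(crit)]
  }
  rng[1] + cut * (rng[2] - rng[1]) / nb
}

#' Segment the animal from the background
#'
#' The rodent is the warmest region of a thermogram, so the foreground mask
#' is simply everything above the top Otsu threshold. If the frame has
#' inverted contrast the mask selects the (wrong) warmest region; that is the
#' definition, not an error. An empty mask is allowed and flagged.
#'
#' @param frame numeric matrix.
#' @param thresholds ascending thresholds from [multilevel_otsu()].
#' @return A list with `mask` (logical matrix), `n_foreground` and `empty`.
#' @export
segment_animal <- function(frame, thresholds) {
  if (is.unsorted(thresholds, strictly = TRUE)) stop("thresholds must be strictly increasing")
  mask <- frame > max(thresholds)
  list(mask = mask, n_foreground = sum(mask), empty = !any(mask))
}

#' Linear contrast stretch to 8-bit
#'
#' Intensities at or below the `lo_pct` percentile map to 0, at or above
#' `hi_pct` to 255, linearly in between (values are rounded to integers).
#' Percentile clipping (defaults 1/99) keeps hot spots such as feces or
#' urine marks from compressing the body's own contrast. The map is monotone
#' non-decreasing in input intensity.
#'
#' @param frame numeric matrix.
#' @param lo_pct,hi_pct clipping percentiles, `0 <= lo_pct < hi_pct <= 100`.
#' @return Integer matrix with values in 0-255.
#' @export
stretch_contrast <- function(frame, lo_pct = 1, hi_pct = 99) {
  if (!(lo_pct >= 0 && lo_pct < hi_pct && hi_pct <= 100))
    stop("need 0 <= lo_pct < hi_pct <= 100")
  lo <- quantile(frame, lo_pct / 100, names = FALSE)
  hi <- quantile(frame, hi_pct / 100, names = FALSE)
  if (hi <= lo) {
    warning("frame has no contrast between the clipping percentiles; returning zeros")
    out <- matrix(0L, nrow(frame), ncol(frame))
    return(out)
  }
  cpp_stretch_frame(frame, lo_pct, hi_pct)
}
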