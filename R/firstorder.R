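#' First-order (histogram) features of an ROI
#'
#' Eighteen intensity-statistics features on the in-mask voxel values of a
#' (possibly filtered) volume. Percentiles use linear interpolation; kurtosis
#' is the excess (normal = 0) convention; entropy and uniformity are computed
#' on the same fixed-bin-number histogram (default 64 bins) as the texture
#' matrices. Zero-variance ROIs return 0 for skewness/kurtosis (degenerate,
#' with a `"degenerate"` attribute set).
#'
#' @param volume A [volume_grid()].
#' @param mask An [roi_mask()] aligned with `volume`, >= 2 voxels.
#' @param n_bins Histogram bins for entropy/uniformity (default 64).
#' @return Named numeric vector of 18 features.
#' @export
firstorder_features <- function(volume, mask, n_bins = 64L) {
  stopifnot(inherits(volume, "volume_grid"), inherits(mask, "roi_mask"))
  stop_if_unaligned(volume, mask)
  x <- volume$values[mask$values]
  n <- length(x)
  if (n < 2L) stop("first-order features need >= 2 in-mask voxels")
  m <- mean(x)
  v <- sum((x - m)^2) / n          # population moments, IBSI style
  degenerate <- v <= 0
  skew <- if (degenerate) 0 else (sum((x - m)^3) / n) / v^1.5
  kurt <- if (degenerate) 0 else (sum((x - m)^4) / n) / v^2 - 3
  q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  in_robust <- x >= q[1] & x <= q[5]
  # histogram probabilities on the fixed-bin discretization
  if (max(x) > min(x)) {
    lev <- pmin(1L + as.integer(floor(n_bins * (x - min(x)) / (max(x) - min(x)))),
                as.integer(n_bins))
    pb <- tabulate(lev, n_bins) / n
  } else {
    pb <- c(1, rep(0, n_bins - 1))
  }
  pb <- pb[pb > 0]
  out <- c(
    mean = m,
    variance = v,
    skewness = skew,
    kurtosis = kurt,
    median = q[3],
    minimum = min(x),
    p10 = q[1],
    p90 = q[5],
    maximum = max(x),
    iqr = q[4] - q[2],
    range = max(x) - min(x),
    mean_abs_dev = mean(abs(x - m)),
    robust_mean_abs_dev = if (any(in_robust)) {
      mean(abs(x[in_robust] - mean(x[in_robust])))
    } else 0,
    coeff_variation = if (m != 0) sqrt(v) / m else 0,
    energy = sum(x^2),
    rms = sqrt(mean(x^2)),
    entropy = -sum(pb * log2(pb)),
    uniformity = sum(pb^2)
  )
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}
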