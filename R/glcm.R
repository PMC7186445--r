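# The 13 unique distance-1 3D directions (one per axis pair, excluding
# antiparallel duplicates): lexicographically positive first nonzero step.
texture_directions <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- (g[, 3] > 0) | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  g[keep, , drop = FALSE]
}

# index windows for pairing a shifted copy of an array along offset d
shift_windows <- function(d, off) {
  lapply(1:3, function(a) {
    if (off[a] >= 0) seq_len(d[a] - off[a]) else (1 - off[a]):d[a]
  })
}

#' Gray-level co-occurrence matrix of a discretized ROI
#'
#' Distance-1 voxel pairs over all 13 unique 3D directions, symmetrized and
#' merged into a single matrix, then normalized to joint probabilities
#' (the single-matrix "merged" aggregation).
#'
#' @param disc A `disc_volume` from [discretize()].
#' @return An `n_bins x n_bins` matrix of probabilities summing to 1.
#' @export
glcm_matrix <- function(disc) {
  stopifnot(inherits(disc, "disc_volume"))
  lev <- disc$levels
  ng <- disc$n_bins
  d <- dim(lev)
  counts <- matrix(0, ng, ng)
  dirs <- texture_directions()
  for (r in seq_len(nrow(dirs))) {
    off <- dirs[r, ]
    wa <- shift_windows(d, off)
    wb <- lapply(1:3, function(a2) wa[[a2]] + off[a2])
    a <- lev[wa[[1]], wa[[2]], wa[[3]]]
    b <- lev[wb[[1]], wb[[2]], wb[[3]]]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    ia <- a[ok]; ib <- b[ok]
    tab <- tabulate((ia - 1L) * ng + ib, nbins = ng * ng)
    counts <- counts + matrix(tab, ng, ng, byrow = TRUE)
  }
  counts <- counts + t(counts)  # symmetrize (adds the antiparallel pairs)
  s <- sum(counts)
  if (s == 0) stop("ROI has no distance-1 voxel pairs")
  counts / s
}

#' GLCM texture features
#'
#' Computes 25 co-occurrence features (IBSI definitions) from the merged,
#' symmetric distance-1 matrix, including cluster shade
#' `sum (i + j - mu_i - mu_j)^3 p(i,j)` and inverse variance
#' `sum_{i != j} p(i,j) / (i - j)^2`. With a single occupied gray level the
#' correlation-type features are degenerate and returned as 0.
#'
#' @param disc A `disc_volume` from [discretize()].
#' @return Named numeric vector of 25 features.
#' @export
glcm_features <- function(disc) {
  p <- glcm_matrix(disc)
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)           # marginal (= colSums by symmetry)
  mu <- sum(seq_len(ng) * px)
  sig2 <- sum((seq_len(ng) - mu)^2 * px)
  sig <- sqrt(sig2)

  # diagonal (difference) and cross (sum) distributions
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), 0)
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(p[(i + j) == k]), 0)

  xlogx <- function(x) ifelse(x > 0, x * log2(x), 0)
  ent <- -sum(xlogx(p))
  hx <- -sum(xlogx(px))
  pxpy <- outer(px, px)
  hxy1 <- -sum(p * ifelse(pxpy > 0, log2(pmax(pxpy, 1e-300)), 0))
  hxy2 <- -sum(xlogx(pxpy))

  da <- sum(k_diff * p_diff)
  off <- i != j
  feats <- c(
    joint_maximum = max(p),
    joint_average = mu,
    joint_variance = sum((i - mu)^2 * p),
    joint_entropy = ent,
    difference_average = da,
    difference_variance = sum((k_diff - da)^2 * p_diff),
    difference_entropy = -sum(xlogx(p_diff)),
    sum_average = sum(k_sum * p_sum),
    sum_variance = sum((k_sum - sum(k_sum * p_sum))^2 * p_sum),
    sum_entropy = -sum(xlogx(p_sum)),
    energy = sum(p^2),
    contrast = sum((i - j)^2 * p),
    dissimilarity = sum(abs(i - j) * p),
    inverse_difference = sum(p / (1 + abs(i - j))),
    inverse_difference_norm = sum(p / (1 + abs(i - j) / ng)),
    inverse_difference_moment = sum(p / (1 + (i - j)^2)),
    inverse_difference_moment_norm = sum(p / (1 + (i - j)^2 / ng^2)),
    inverse_variance = sum(p[off] / (i[off] - j[off])^2),
    correlation = if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 0,
    autocorrelation = sum(i * j * p),
    cluster_tendency = sum((i + j - 2 * mu)^2 * p),
    cluster_shade = sum((i + j - 2 * mu)^3 * p),
    cluster_prominence = sum((i + j - 2 * mu)^4 * p),
    info_corr_1 = if (hx > 0) (ent - hxy1) / hx else 0,
    info_corr_2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  )
  feats
}
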