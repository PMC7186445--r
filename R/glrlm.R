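#' Gray-level run-length matrix of a discretized ROI
#'
#' Runs of consecutive voxels sharing a gray level are extracted along each
#' of the 13 unique 3D directions, restricted to in-ROI voxels (leaving the
#' ROI breaks a run), and the per-direction counts are summed into a single
#' matrix (merged aggregation).
#'
#' @param disc A `disc_volume` from [discretize()].
#' @return List with `r` (`n_bins x max_run` count matrix), `n_runs`,
#'   `n_voxels` (in-ROI voxel count) and `n_directions` (13).
#' @export
glrlm_matrix <- function(disc) {
  stopifnot(inherits(disc, "disc_volume"))
  lev <- disc$levels
  d <- dim(lev)
  ng <- disc$n_bins
  dirs <- texture_directions()
  max_run <- max(d)
  counts <- matrix(0, ng, max_run)

  coords <- arrayInd(seq_along(lev), d)
  vals <- as.vector(lev)
  for (r in seq_len(nrow(dirs))) {
    off <- dirs[r, ]
    k <- which(off != 0)[1]           # parameter axis: unit step along line
    t <- coords[, k] * off[k]         # off[k] is +-1 -> strictly increasing
    # line id: voxel position minus t * off, collapsed to a scalar key
    li <- coords - outer(t, off)
    M <- max(d)
    key <- (li[, 1] + M) + (li[, 2] + M) * (3 * M + 1) +
      (li[, 3] + M) * (3 * M + 1)^2
    ord <- order(key, t)
    v <- vals[ord]; kk <- key[ord]
    same_line <- c(FALSE, diff(kk) == 0)
    new_run <- !same_line | c(TRUE, v[-1] != v[-length(v)]) |
      is.na(v) | c(TRUE, is.na(v[-length(v)]))
    run_id <- cumsum(new_run)
    keep <- !is.na(v)
    if (!any(keep)) next
    runs <- rle(run_id[keep])
    rl <- runs$lengths
    starts <- cumsum(c(1L, rl[-length(rl)]))
    rg <- v[keep][starts]
    counts <- counts + matrix(tabulate((rl - 1L) * ng + rg, nbins = ng * max_run),
                              ng, max_run)
  }
  list(r = counts, n_runs = sum(counts),
       n_voxels = sum(!is.na(lev)), n_directions = nrow(dirs))
}

#' GLRLM texture features
#'
#' Computes 14 run-length features from the merged run-length matrix,
#' including run-length non-uniformity `RLN = sum_j (sum_i r(i,j))^2 / N_r`
#' and its normalized variant `RLNN = RLN / N_r`. Run percentage uses the
#' direction-summed accounting `N_r / (13 * N_v)`.
#'
#' @param disc A `disc_volume` from [discretize()].
#' @return Named numeric vector of 14 features.
#' @export
glrlm_features <- function(disc) {
  m <- glrlm_matrix(disc)
  r <- m$r
  nr <- m$n_runs
  i <- matrix(seq_len(nrow(r)), nrow(r), ncol(r))
  j <- t(matrix(seq_len(ncol(r)), ncol(r), nrow(r)))
  rg <- rowSums(r)  # per gray level
  rj <- colSums(r)  # per run length
  p <- r / nr
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  c(
    short_run_emphasis = sum(rj / seq_along(rj)^2) / nr,
    long_run_emphasis = sum(rj * seq_along(rj)^2) / nr,
    low_gl_run_emphasis = sum(rg / seq_along(rg)^2) / nr,
    high_gl_run_emphasis = sum(rg * seq_along(rg)^2) / nr,
    short_run_low_gl_emphasis = sum(r / (i^2 * j^2)) / nr,
    short_run_high_gl_emphasis = sum(r * i^2 / j^2) / nr,
    long_run_low_gl_emphasis = sum(r * j^2 / i^2) / nr,
    long_run_high_gl_emphasis = sum(r * i^2 * j^2) / nr,
    gl_nonuniformity = sum(rg^2) / nr,
    run_length_nonuniformity = sum(rj^2) / nr,
    run_length_nonuniformity_norm = sum(rj^2) / nr^2,
    run_percentage = nr / (m$n_voxels * m$n_directions),
    gl_variance = sum((i - mu_i)^2 * p),
    run_length_variance = sum((j - mu_j)^2 * p)
  )
}
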