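# Independent brute-force oracles used to validate the texture machinery.
# Deliberately naive: explicit loops over voxels, pairs and runs.

make_disc <- function(levels, n_bins = max(levels, na.rm = TRUE)) {
  structure(list(levels = levels, n_bins = as.integer(n_bins),
                 range = range(levels, na.rm = TRUE), spacing = c(1, 1, 1)),
            class = "disc_volume")
}

all_26_directions <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

half_13_directions <- function() {
  g <- all_26_directions()
  g[(g[, 3] > 0) | (g[, 3] == 0 & g[, 2] > 0) |
      (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0), , drop = FALSE]
}

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

# symmetric merged co-occurrence probabilities by explicit pair enumeration
bf_glcm <- function(lev, ng) {
  d <- dim(lev)
  cnt <- matrix(0, ng, ng)
  dirs <- all_26_directions()
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    for (r in seq_len(nrow(dirs))) {
      q <- c(x, y, z) + dirs[r, ]
      if (!in_grid(q, d)) next
      b <- lev[q[1], q[2], q[3]]
      if (is.na(b)) next
      cnt[a, b] <- cnt[a, b] + 1
    }
  }
  cnt / sum(cnt)
}

# straightforward (independent) feature formulas from a GLCM
bf_glcm_features <- function(p) {
  ng <- nrow(p)
  f <- list()
  px <- rowSums(p)
  mu <- sum((1:ng) * px)
  f$cluster_shade <- 0; f$contrast <- 0; f$inverse_variance <- 0
  f$correlation_num <- 0; f$joint_entropy <- 0
  sig2 <- sum(((1:ng) - mu)^2 * px)
  for (i in 1:ng) for (j in 1:ng) {
    pij <- p[i, j]
    f$cluster_shade <- f$cluster_shade + (i + j - 2 * mu)^3 * pij
    f$contrast <- f$contrast + (i - j)^2 * pij
    if (i != j) f$inverse_variance <- f$inverse_variance + pij / (i - j)^2
    f$correlation_num <- f$correlation_num + i * j * pij
    if (pij > 0) f$joint_entropy <- f$joint_entropy - pij * log2(pij)
  }
  f$correlation <- if (sig2 > 0) (f$correlation_num - mu^2) / sig2 else 0
  f
}

# run-length matrix by explicit run walking per direction
bf_glrlm <- function(lev) {
  d <- dim(lev)
  ng <- max(lev, na.rm = TRUE)
  dirs <- half_13_directions()
  counts <- matrix(0, ng, max(d))
  for (r in seq_len(nrow(dirs))) {
    off <- dirs[r, ]
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      v <- lev[x, y, z]
      if (is.na(v)) next
      prev <- c(x, y, z) - off
      if (in_grid(prev, d) && !is.na(lev[prev[1], prev[2], prev[3]]) &&
          lev[prev[1], prev[2], prev[3]] == v) next  # not a run start
      len <- 0L; cur <- c(x, y, z)
      while (in_grid(cur, d) && !is.na(lev[cur[1], cur[2], cur[3]]) &&
             lev[cur[1], cur[2], cur[3]] == v) {
        len <- len + 1L
        cur <- cur + off
      }
      counts[v, len] <- counts[v, len] + 1
    }
  }
  counts
}

bf_rln <- function(counts) {
  nr <- sum(counts)
  rj <- colSums(counts)
  c(rln = sum(rj^2) / nr, rlnn = sum(rj^2) / nr^2)
}

# independent even-odd point-in-polygon (ray casting, counts crossings)
bf_point_in_polygon <- function(qx, qy, px, py) {
  n <- length(px)
  cross <- 0L
  j <- n
  for (i in seq_len(n)) {
    if ((py[i] > qy) != (py[j] > qy)) {
      xint <- px[i] + (qy - py[i]) / (py[j] - py[i]) * (px[j] - px[i])
      if (qx < xint) cross <- cross + 1L
    }
    j <- i
  }
  cross %% 2L == 1L
}

# ball mask helper
ball_mask <- function(radius, spacing = c(1, 1, 1), pad = 3) {
  n <- ceiling(2 * radius / spacing) + 2 * pad + 1
  cc <- (n + 1) / 2
  d <- as.integer(n)
  arr <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    dz2 <- ((k - cc[3]) * spacing[3])^2
    dx <- ((seq_len(d[1]) - cc[1]) * spacing[1])^2
    dy <- ((seq_len(d[2]) - cc[2]) * spacing[2])^2
    arr[, , k] <- outer(dx, dy, `+`) + dz2 <= radius^2
  }
  roi_mask(arr, spacing)
}
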