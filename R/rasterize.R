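#' Rasterize planar contours into an ROI mask
#'
#' Converts per-slice closed polygons (physical mm coordinates, as exported
#' from a treatment planning system) into a binary mask on a reference grid.
#' A voxel belongs to the ROI iff its center lies inside the polygon of its
#' slice under the even-odd rule; multiple polygons on one slice are unioned.
#'
#' @param contours List of contours; each a list/data.frame with numeric
#'   fields `x`, `y` (mm, polygon vertices, closed implicitly) and scalar `z`
#'   (mm, slice position).
#' @param reference A [volume_grid()] supplying the output geometry.
#' @param roi_name Name for the resulting mask.
#' @return An [roi_mask()] aligned with `reference`.
#' @export
rasterize_contours <- function(contours, reference, roi_name = "roi") {
  stopifnot(inherits(reference, "volume_grid"))
  d <- dim(reference$values)
  inside <- array(FALSE, d)
  xs <- reference$origin[1] + (seq_len(d[1]) - 1) * reference$spacing[1]
  ys <- reference$origin[2] + (seq_len(d[2]) - 1) * reference$spacing[2]
  zs <- reference$origin[3] + (seq_len(d[3]) - 1) * reference$spacing[3]
  pts <- cbind(rep(xs, times = d[2]), rep(ys, each = d[1]))

  for (ct in contours) {
    px <- as.numeric(ct$x); py <- as.numeric(ct$y); pz <- as.numeric(ct$z[1])
    if (length(px) < 3L || length(px) != length(py)) {
      stop("each contour needs >= 3 (x, y) vertices")
    }
    k <- which.min(abs(zs - pz))
    if (abs(zs[k] - pz) > reference$spacing[3] / 2 + 1e-9) {
      warning(sprintf("contour at z = %g mm lies outside the grid; skipped", pz))
      next
    }
    odd <- point_in_polygon(pts[, 1], pts[, 2], px, py)
    inside[, , k] <- inside[, , k] | matrix(odd, d[1], d[2])
  }
  roi_mask(inside, reference$spacing, reference$origin, roi_name)
}

# Even-odd (crossing number) point-in-polygon test, vectorized over points.
# Points exactly on a horizontal edge follow the half-open ray convention.
point_in_polygon <- function(qx, qy, px, py) {
  n <- length(px)
  inside <- logical(length(qx))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > qy) != (py[j] > qy))
    if (any(crosses)) {
      xint <- px[i] + (qy[crosses] - py[i]) / (py[j] - py[i]) * (px[j] - px[i])
      inside[crosses] <- xor(inside[crosses], qx[crosses] < xint)
    }
    j <- i
  }
  inside
}
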