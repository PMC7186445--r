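#' 3D scalar volume on a regular grid
#'
#' The container used for CT images (HU), relative electron density (RED),
#' physical dose (Gy) and biologically effective dose (BED, Gy). Values are
#' stored in an `[x, y, z]` array; the physical coordinate of voxel
#' `(i, j, k)` (1-based) is `origin + (c(i, j, k) - 1) * spacing`, i.e. the
#' convention is voxel *centers* on a regular lattice in patient millimetres.
#'
#' @param values Numeric 3D array.
#' @param spacing Numeric length-3 voxel spacing in mm, all `> 0`.
#' @param origin Numeric length-3 physical position (mm) of the first voxel
#'   center. Default `c(0, 0, 0)`.
#' @return A `volume_grid` object.
#' @export
volume_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3D array")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive finite numbers (mm)")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite numbers (mm)")
  }
  if (any(!is.finite(values))) stop("`values` must be finite everywhere")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' Binary region-of-interest mask aligned to a volume grid
#'
#' @param values Logical (or 0/1) 3D array.
#' @param spacing,origin Grid geometry, as in [volume_grid()].
#' @param roi_name Name of the region (e.g. `"breast"`, `"ptv"`).
#' @return An `roi_mask` object (also a `volume_grid` of logicals).
#' @export
roi_mask <- function(values, spacing, origin = c(0, 0, 0), roi_name = "roi") {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("mask `values` must be a 3D array")
  }
  if (!is.logical(values)) {
    if (!all(values %in% c(0, 1))) stop("mask values must be binary")
    values <- array(values != 0, dim = dim(values))
  }
  g <- volume_grid(array(0, dim(values)), spacing, origin)
  g$values <- values
  g$roi_name <- as.character(roi_name)
  class(g) <- c("roi_mask", "volume_grid")
  g
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              if (inherits(x, "roi_mask")) paste0("roi_mask:", x$roi_name)
              else "volume_grid",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  if (inherits(x, "roi_mask")) {
    cat(sprintf("  %d voxels set (%.1f%%)\n", sum(x$values),
                100 * mean(x$values)))
  } else {
    cat(sprintf("  value range [%g, %g]\n", min(x$values), max(x$values)))
  }
  invisible(x)
}

# TRUE if two grids share shape and geometry (within tolerance)
grids_aligned <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_unaligned <- function(vol, mask, what = "mask") {
  if (!grids_aligned(vol, mask)) {
    stop(sprintf("%s is not aligned with the volume grid (shape/spacing/origin differ)",
                 what))
  }
  invisible(TRUE)
}

# bounding box (list of index ranges) of a mask, with optional voxel padding
mask_bbox <- function(mask, pad = 0L) {
  idx <- which(mask$values, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop(sprintf("ROI '%s' is empty", mask$roi_name %||% "roi"))
  d <- dim(mask$values)
  lo <- pmax(1L, apply(idx, 2, min) - pad)
  hi <- pmin(d, apply(idx, 2, max) + pad)
  list(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
}

crop_grid <- function(g, bbox) {
  vals <- g$values[bbox$x, bbox$y, bbox$z, drop = FALSE]
  new_origin <- g$origin + (c(bbox$x[1], bbox$y[1], bbox$z[1]) - 1) * g$spacing
  if (inherits(g, "roi_mask")) {
    roi_mask(vals, g$spacing, new_origin, g$roi_name)
  } else {
    volume_grid(vals, g$spacing, new_origin)
  }
}
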