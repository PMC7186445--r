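#' Write a volume to a NIfTI research file
#'
#' Values, spacing and origin round-trip losslessly (float64 storage). Masks
#' are written as 0/1 bytes.
#'
#' @param volume A [volume_grid()] or [roi_mask()].
#' @param file Output path ending in `.nii` or `.nii.gz`.
#' @return `file`, invisibly.
#' @export
write_volume <- function(volume, file) {
  stopifnot(inherits(volume, "volume_grid"))
  check_volume_ext(file)
  vals <- volume$values
  if (is.logical(vals)) {
    vals <- array(as.integer(vals), dim(vals))
    dt <- "uint8"
  } else {
    dt <- "double"
  }
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- volume$spacing
  m <- diag(c(volume$spacing, 1))
  m[1:3, 4] <- volume$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, file, datatype = dt)
  invisible(file)
}

#' Read a volume from a NIfTI research file
#'
#' @param file Path ending in `.nii` or `.nii.gz`.
#' @param as_mask If `TRUE`, return an [roi_mask()] (values must be 0/1).
#' @param roi_name ROI name used when `as_mask = TRUE`.
#' @return A [volume_grid()] or [roi_mask()].
#' @export
read_volume <- function(file, as_mask = FALSE, roi_name = "roi") {
  check_volume_ext(file)
  if (!file.exists(file)) stop("file not found: ", file)
  img <- RNifti::readNifti(file)
  vals <- as.array(img)
  if (length(dim(vals)) != 3L) stop("expected a 3D volume in ", file)
  spacing <- RNifti::pixdim(img)[1:3]
  x <- RNifti::xform(img)
  origin <- as.numeric(x[1:3, 4])
  vals <- array(as.numeric(vals), dim(vals))
  if (as_mask) {
    roi_mask(vals, spacing, origin, roi_name)
  } else {
    volume_grid(vals, spacing, origin)
  }
}

check_volume_ext <- function(file) {
  if (!grepl("\\.nii(\\.gz)?$", file)) {
    stop("unsupported volume format for '", file,
         "'; supported: .nii, .nii.gz (NIfTI)")
  }
  invisible(TRUE)
}

#' Resample a volume to a new isotropic (or anisotropic) spacing
#'
#' Standardizes voxel spacing before feature extraction (the analysis grid is
#' 3 x 3 x 3 mm by default). Continuous volumes are interpolated trilinearly;
#' masks use nearest-neighbour so the output remains binary. The output lattice
#' keeps the input origin and covers the same physical extent to within one
#' voxel.
#'
#' @param volume A [volume_grid()] or [roi_mask()].
#' @param target_spacing Numeric length-3 (or length-1, recycled) spacing in mm.
#' @param mode `"continuous"` (trilinear) or `"mask"` (nearest neighbour).
#'   Defaults to `"mask"` for `roi_mask` input, `"continuous"` otherwise.
#' @return A resampled [volume_grid()] or [roi_mask()].
#' @export
resample <- function(volume, target_spacing,
                     mode = if (inherits(volume, "roi_mask")) "mask" else "continuous") {
  stopifnot(inherits(volume, "volume_grid"))
  mode <- match.arg(mode, c("continuous", "mask"))
  target_spacing <- rep_len(as.numeric(target_spacing), 3L)
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0)) {
    stop("`target_spacing` must be positive")
  }
  d <- dim(volume$values)
  extent <- (d - 1) * volume$spacing
  nd <- pmax(1L, as.integer(floor(extent / target_spacing + 1e-9)) + 1L)
  if (prod(nd) == 0) stop("resampling produced an empty grid")

  # fractional source indices of each target sample, per axis (1-based)
  ax <- lapply(1:3, function(a) {
    t_phys <- (seq_len(nd[a]) - 1) * target_spacing[a]
    f <- t_phys / volume$spacing[a] + 1
    pmin(pmax(f, 1), d[a])
  })

  if (mode == "mask") {
    src <- lapply(1:3, function(a) as.integer(round(ax[[a]])))
    vals <- volume$values[src[[1]], src[[2]], src[[3]], drop = FALSE]
    out <- roi_mask(vals, target_spacing, volume$origin,
                    volume$roi_name %||% "roi")
    return(out)
  }

  f1 <- ax[[1]]; f2 <- ax[[2]]; f3 <- ax[[3]]
  i0 <- pmin(floor(f1), d[1] - 1L); w1 <- f1 - i0
  j0 <- pmin(floor(f2), d[2] - 1L); w2 <- f2 - j0
  k0 <- pmin(floor(f3), d[3] - 1L); w3 <- f3 - k0
  if (d[1] == 1L) { i0 <- rep(1, nd[1]); w1 <- rep(0, nd[1]) }
  if (d[2] == 1L) { j0 <- rep(1, nd[2]); w2 <- rep(0, nd[2]) }
  if (d[3] == 1L) { k0 <- rep(1, nd[3]); w3 <- rep(0, nd[3]) }

  out <- array(0, nd)
  v <- volume$values
  for (dz in 0:1) {
    kz <- pmin(k0 + dz, d[3]); wz <- if (dz == 0) 1 - w3 else w3
    for (dy in 0:1) {
      jy <- pmin(j0 + dy, d[2]); wy <- if (dy == 0) 1 - w2 else w2
      for (dx in 0:1) {
        ix <- pmin(i0 + dx, d[1]); wx <- if (dx == 0) 1 - w1 else w1
        corner <- v[ix, jy, kz, drop = FALSE]
        w <- outer(outer(wx, wy), wz)
        out <- out + w * corner
      }
    }
  }
  volume_grid(out, target_spacing, volume$origin)
}
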