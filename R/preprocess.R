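#' Scanner HU-to-RED calibration curve
#'
#' Tabulated (HU, relative electron density) control points as measured on a
#' density phantom for one CT scanner. Conversion removes the dependency on
#' the scanner's Hounsfield scale before texture analysis.
#'
#' @param hu Numeric vector of Hounsfield units, strictly increasing.
#' @param red Numeric vector of relative electron densities (water = 1),
#'   non-negative and non-decreasing.
#' @return A `calibration_curve` object.
#' @export
calibration_curve <- function(hu, red) {
  hu <- as.numeric(hu); red <- as.numeric(red)
  if (length(hu) < 2L || length(hu) != length(red)) {
    stop("calibration curve needs >= 2 (hu, red) control points")
  }
  if (any(diff(hu) <= 0)) stop("HU control points must be strictly increasing")
  if (any(red < 0) || any(diff(red) < 0)) {
    stop("RED control points must be non-negative and non-decreasing")
  }
  structure(list(hu = hu, red = red), class = "calibration_curve")
}

#' Default HU-to-RED calibration
#'
#' A generic two-segment curve (air/lung/water/soft tissue/bone) of the kind
#' measured on CT density phantoms; adequate for synthetic cohorts. Real
#' studies should supply the per-scanner measured curve.
#'
#' @return A [calibration_curve()].
#' @export
default_calibration <- function() {
  calibration_curve(
    hu = c(-1000, -500, -100, 0, 60, 1000, 3000),
    red = c(0.001, 0.49, 0.93, 1.0, 1.05, 1.56, 2.6)
  )
}

#' Convert a CT volume from Hounsfield units to relative electron density
#'
#' Piecewise-linear interpolation between calibration control points; beyond
#' the endpoints the terminal segment is continued linearly and the result is
#' clamped at 0 (electron density cannot be negative).
#'
#' @param ct A [volume_grid()] in HU.
#' @param curve A [calibration_curve()].
#' @return A [volume_grid()] of relative electron density (water = 1).
#' @export
hu_to_red <- function(ct, curve = default_calibration()) {
  stopifnot(inherits(ct, "volume_grid"), inherits(curve, "calibration_curve"))
  x <- curve$hu; y <- curve$red
  n <- length(x)
  slope_lo <- (y[2] - y[1]) / (x[2] - x[1])
  slope_hi <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  v <- ct$values
  red <- stats::approx(x, y, xout = as.vector(v), rule = 2)$y
  below <- as.vector(v) < x[1]
  above <- as.vector(v) > x[n]
  red[below] <- y[1] + slope_lo * (as.vector(v)[below] - x[1])
  red[above] <- y[n] + slope_hi * (as.vector(v)[above] - x[n])
  red <- pmax(red, 0)
  volume_grid(array(red, dim(v)), ct$spacing, ct$origin)
}

#' Fractionation scheme
#'
#' @param total_dose Prescription dose in Gy (>= 0).
#' @param n_fractions Number of fractions (positive integer).
#' @param alpha_beta Tissue alpha/beta ratio in Gy (> 0); 3 Gy is typical of
#'   late-responding subcutaneous tissue and is the default used throughout.
#' @return A `fractionation_scheme` object.
#' @export
fractionation_scheme <- function(total_dose, n_fractions, alpha_beta = 3) {
  if (!is.numeric(total_dose) || total_dose < 0) stop("total_dose must be >= 0")
  if (!is.numeric(n_fractions) || n_fractions <= 0 ||
      n_fractions != round(n_fractions)) {
    stop("n_fractions must be a positive integer")
  }
  if (!is.numeric(alpha_beta) || alpha_beta <= 0) stop("alpha_beta must be > 0")
  structure(list(total_dose = total_dose, n_fractions = as.integer(n_fractions),
                 alpha_beta = alpha_beta),
            class = "fractionation_scheme")
}

#' Convert a physical dose volume to biologically effective dose (BED)
#'
#' Linear-quadratic model with uniform fraction size per voxel: a voxel
#' receiving total physical dose D in n fractions (fraction size d = D/n) has
#' `BED = D * (1 + (D/n) / (alpha/beta))`. Converting to BED makes texture
#' features comparable across patients treated with different
#' hypofractionation schemes.
#'
#' @param dose A [volume_grid()] of physical dose in Gy, all values >= 0.
#' @param scheme A [fractionation_scheme()] supplying `n_fractions` and
#'   `alpha_beta`.
#' @return A [volume_grid()] of BED in Gy.
#' @export
dose_to_bed <- function(dose, scheme) {
  stopifnot(inherits(dose, "volume_grid"), inherits(scheme, "fractionation_scheme"))
  if (any(dose$values < 0)) stop("dose must be >= 0 everywhere")
  D <- dose$values
  bed <- D * (1 + (D / scheme$n_fractions) / scheme$alpha_beta)
  volume_grid(bed, dose$spacing, dose$origin)
}

#' Image filter specification
#'
#' @param kind One of `"none"`, `"gaussian"`, `"log"` (Laplacian of
#'   Gaussian), `"median"`.
#' @param scale For `gaussian`/`log`: sigma in mm (default 3 mm). For
#'   `median`: kernel half-width in voxels (default 1, i.e. 3 x 3 x 3).
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(kind = c("none", "gaussian", "log", "median"),
                        scale = NULL) {
  kind <- match.arg(kind)
  if (is.null(scale)) scale <- if (kind == "median") 1 else 3
  if (kind != "none" && (!is.numeric(scale) || scale <= 0)) {
    stop("filter scale must be > 0")
  }
  structure(list(kind = kind, scale = scale), class = "filter_spec")
}

#' Apply a 3D filter to a volume
#'
#' Filtering is done in physical units: Gaussian/LoG sigma is given in mm and
#' converted per axis to voxels using the grid spacing. Boundaries are handled
#' by edge replication. `kind = "none"` is the identity.
#'
#' @param volume A [volume_grid()].
#' @param spec A [filter_spec()].
#' @return A filtered [volume_grid()].
#' @export
apply_filter <- function(volume, spec) {
  stopifnot(inherits(volume, "volume_grid"), inherits(spec, "filter_spec"))
  out <- switch(spec$kind,
    none = volume$values,
    gaussian = gaussian_3d(volume$values, spec$scale / volume$spacing),
    log = log_3d(volume$values, spec$scale, volume$spacing),
    median = median_3d(volume$values, as.integer(spec$scale))
  )
  volume_grid(out, volume$spacing, volume$origin)
}

# separable Gaussian, sigma given per axis in voxels
gaussian_3d <- function(a, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s < 1e-8) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    a <- conv_axis(a, k, axis)
  }
  a
}

# convolve along one axis with edge replication
conv_axis <- function(a, k, axis) {
  d <- dim(a)
  r <- (length(k) - 1L) / 2L
  idx_pad <- c(rep(1L, r), seq_len(d[axis]), rep(d[axis], r))
  ap <- switch(axis,
    a[idx_pad, , , drop = FALSE],
    a[, idx_pad, , drop = FALSE],
    a[, , idx_pad, drop = FALSE])
  out <- array(0, d)
  for (t in seq_along(k)) {
    sl <- (t - 1L) + seq_len(d[axis])
    out <- out + k[t] * switch(axis,
      ap[sl, , , drop = FALSE],
      ap[, sl, , drop = FALSE],
      ap[, , sl, drop = FALSE])
  }
  out
}

# Laplacian of Gaussian: Gaussian smoothing (sigma mm) then a finite-difference
# Laplacian in physical (1/mm^2) units, edge-replicated
log_3d <- function(a, sigma_mm, spacing) {
  g <- gaussian_3d(a, sigma_mm / spacing)
  d <- dim(g)
  lap <- array(0, d)
  for (axis in 1:3) {
    n <- d[axis]
    ip <- c(2:n, n); im <- c(1, 1:(n - 1))
    plus <- switch(axis, g[ip, , , drop = FALSE], g[, ip, , drop = FALSE],
                   g[, , ip, drop = FALSE])
    minus <- switch(axis, g[im, , , drop = FALSE], g[, im, , drop = FALSE],
                    g[, , im, drop = FALSE])
    lap <- lap + (plus - 2 * g + minus) / spacing[axis]^2
  }
  lap
}

# median filter with (2w+1)^3 neighbourhood, edge replication
median_3d <- function(a, w) {
  d <- dim(a)
  offs <- expand.grid(dx = -w:w, dy = -w:w, dz = -w:w)
  m <- matrix(0, length(a), nrow(offs))
  ix <- function(n, o) pmin(pmax(seq_len(n) + o, 1L), n)
  for (t in seq_len(nrow(offs))) {
    m[, t] <- as.vector(a[ix(d[1], offs$dx[t]), ix(d[2], offs$dy[t]),
                          ix(d[3], offs$dz[t])])
  }
  array(apply(m, 1, stats::median), d)
}

#' Discretize in-mask intensities into equally spaced bins
#'
#' Fixed-bin-number scheme over the in-mask `[min, max]` range: level
#' `= 1 + floor(n_bins * (x - min) / (max - min))`, with the maximum mapped
#' to `n_bins`. 64 bins is the default used for all texture matrices.
#'
#' @param volume A [volume_grid()].
#' @param mask An [roi_mask()] aligned with `volume`, nonempty.
#' @param n_bins Number of gray levels (default 64).
#' @return A `disc_volume`: integer levels in `1..n_bins` inside the mask,
#'   `NA` outside, plus binning metadata.
#' @export
discretize <- function(volume, mask, n_bins = 64L) {
  stopifnot(inherits(volume, "volume_grid"), inherits(mask, "roi_mask"))
  stop_if_unaligned(volume, mask)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  inm <- mask$values
  if (!any(inm)) stop("mask is empty")
  x <- volume$values[inm]
  lo <- min(x); hi <- max(x)
  lev <- array(NA_integer_, dim(volume$values))
  if (hi == lo) {
    warning("degenerate ROI: all in-mask intensities equal; single level used")
    lev[inm] <- 1L
  } else {
    l <- 1L + as.integer(floor(n_bins * (x - lo) / (hi - lo)))
    l[l > n_bins] <- n_bins
    lev[inm] <- l
  }
  structure(list(levels = lev, n_bins = n_bins, range = c(lo, hi),
                 spacing = volume$spacing),
            class = "disc_volume")
}
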