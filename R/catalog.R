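firstorder_names <- function() {
  c("mean", "variance", "skewness", "kurtosis", "median", "minimum", "p10",
    "p90", "maximum", "iqr", "range", "mean_abs_dev", "robust_mean_abs_dev",
    "coeff_variation", "energy", "rms", "entropy", "uniformity")
}

glcm_names <- function() {
  c("joint_maximum", "joint_average", "joint_variance", "joint_entropy",
    "difference_average", "difference_variance", "difference_entropy",
    "sum_average", "sum_variance", "sum_entropy", "energy", "contrast",
    "dissimilarity", "inverse_difference", "inverse_difference_norm",
    "inverse_difference_moment", "inverse_difference_moment_norm",
    "inverse_variance", "correlation", "autocorrelation", "cluster_tendency",
    "cluster_shade", "cluster_prominence", "info_corr_1", "info_corr_2")
}

glrlm_names <- function() {
  c("short_run_emphasis", "long_run_emphasis", "low_gl_run_emphasis",
    "high_gl_run_emphasis", "short_run_low_gl_emphasis",
    "short_run_high_gl_emphasis", "long_run_low_gl_emphasis",
    "long_run_high_gl_emphasis", "gl_nonuniformity",
    "run_length_nonuniformity", "run_length_nonuniformity_norm",
    "run_percentage", "gl_variance", "run_length_variance")
}

shape_names <- function() {
  c("voxel_count", "volume_mm3", "surface_area_mm2", "surface_volume_ratio",
    "sphericity", "compactness1", "compactness2", "spherical_disproportion",
    "asphericity", "equivalent_diameter", "max_3d_diameter",
    "major_axis_length", "minor_axis_length", "least_axis_length",
    "elongation", "flatness", "aabb_volume_density", "aabb_area_density",
    "ellipsoid_volume_density", "ellipsoid_area_density", "com_shift_mm")
}

#' The default radiomics feature catalog
#'
#' Enumerates every feature column the extractor produces: 21 shape features
#' per ROI (computed once per ROI, on the mask geometry) plus 57 intensity
#' features (18 first-order + 25 GLCM + 14 GLRLM) per combination of image
#' (RED, BED), ROI (breast, PTV) and filter (none, Gaussian, LoG, median).
#' With the defaults that is `21*2 + 57*2*2*4 = 954` columns. Column names
#' follow `<image>_<filter>_<roi>_<family>_<feature>` (shape:
#' `shape_<roi>_<feature>`).
#'
#' @param images Character vector of image names (default `c("red", "bed")`).
#' @param rois Character vector of ROI names (default `c("breast", "ptv")`).
#' @param filters Character vector of filter names
#'   (default `c("none", "gaussian", "log", "median")`).
#' @return Data frame with columns `family`, `feature`, `image`, `roi`,
#'   `filter`, `name`.
#' @export
feature_catalog <- function(images = c("red", "bed"),
                            rois = c("breast", "ptv"),
                            filters = c("none", "gaussian", "log", "median")) {
  shape <- expand.grid(feature = shape_names(), roi = rois,
                       stringsAsFactors = FALSE)
  shape$family <- "shape"
  shape$image <- NA_character_
  shape$filter <- NA_character_
  shape$name <- paste("shape", shape$roi, shape$feature, sep = "_")

  fam <- rbind(
    data.frame(family = "firstorder", feature = firstorder_names()),
    data.frame(family = "glcm", feature = glcm_names()),
    data.frame(family = "glrlm", feature = glrlm_names())
  )
  tex <- merge(merge(merge(fam, data.frame(image = images)),
                     data.frame(roi = rois)),
               data.frame(filter = filters))
  tex$name <- paste(tex$image, tex$filter, tex$roi, tex$family, tex$feature,
                    sep = "_")
  out <- rbind(shape[, c("family", "feature", "image", "roi", "filter", "name")],
               tex[, c("family", "feature", "image", "roi", "filter", "name")])
  stopifnot(!anyDuplicated(out$name))
  rownames(out) <- NULL
  out
}

#' Extract all catalog features for one patient
#'
#' For every (image, ROI, filter) combination in the catalog the volume is
#' cropped to the ROI bounding box (with a filter-support margin), filtered,
#' discretized to `n_bins` levels over the in-ROI range of the *filtered*
#' intensities, and the first-order/GLCM/GLRLM features are computed. Shape
#' features are computed once per ROI from the mask (intensity-weighted
#' center-of-mass shift uses the unfiltered RED volume). Deterministic.
#'
#' @param red RED [volume_grid()] (relative electron density).
#' @param bed BED [volume_grid()], aligned with `red`.
#' @param breast,ptv [roi_mask()]s aligned with the volumes.
#' @param catalog Catalog from [feature_catalog()].
#' @param n_bins Discretization bins (default 64).
#' @param filter_scales Named list of [filter_spec()] scales:
#'   `gaussian`/`log` sigma in mm (default 3), `median` half-width in voxels
#'   (default 1).
#' @return Named numeric vector with exactly the catalog's columns.
#' @export
extract_all <- function(red, bed, breast, ptv, catalog = feature_catalog(),
                        n_bins = 64L,
                        filter_scales = list(gaussian = 3, log = 3, median = 1)) {
  images <- list(red = red, bed = bed)
  rois <- list(breast = breast, ptv = ptv)
  for (nm in unique(stats::na.omit(catalog$image))) {
    if (is.null(images[[nm]])) stop("no volume supplied for image '", nm, "'")
  }
  for (nm in unique(catalog$roi)) {
    if (is.null(rois[[nm]])) stop("no mask supplied for ROI '", nm, "'")
    stop_if_unaligned(red, rois[[nm]], paste0("ROI '", nm, "'"))
    stop_if_unaligned(bed, rois[[nm]], paste0("ROI '", nm, "'"))
  }
  out <- rep(NA_real_, nrow(catalog))
  names(out) <- catalog$name

  # shape once per ROI
  for (nm in unique(catalog$roi[catalog$family == "shape"])) {
    sf <- suppressWarnings(shape_features(rois[[nm]], volume = red))
    sel <- catalog$family == "shape" & catalog$roi == nm
    out[catalog$name[sel]] <- sf[catalog$feature[sel]]
  }

  tex <- catalog[catalog$family != "shape", ]
  combos <- unique(tex[, c("image", "roi", "filter")])
  for (r in seq_len(nrow(combos))) {
    img_nm <- combos$image[r]; roi_nm <- combos$roi[r]; flt <- combos$filter[r]
    mask <- rois[[roi_nm]]
    pad <- filter_pad(flt, filter_scales, images[[img_nm]]$spacing)
    bb <- mask_bbox(mask, pad = pad)
    vol_c <- crop_grid(images[[img_nm]], bb)
    mask_c <- crop_grid(mask, bb)
    spec <- filter_spec(flt, scale = filter_scales[[flt]] %||% NULL)
    filt <- apply_filter(vol_c, spec)
    disc <- suppressWarnings(discretize(filt, mask_c, n_bins))
    vals <- c(
      firstorder = list(suppressWarnings(firstorder_features(filt, mask_c, n_bins))),
      glcm = list(glcm_features(disc)),
      glrlm = list(glrlm_features(disc))
    )
    sel <- tex$image == img_nm & tex$roi == roi_nm & tex$filter == flt
    rows <- tex[sel, ]
    for (fam in unique(rows$family)) {
      fr <- rows[rows$family == fam, ]
      out[fr$name] <- vals[[fam]][fr$feature]
    }
  }
  if (any(!is.finite(out))) {
    bad <- names(out)[!is.finite(out)]
    stop("non-finite feature values: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  out
}

filter_pad <- function(flt, scales, spacing) {
  switch(flt,
    none = 1L,
    gaussian = as.integer(ceiling(3 * (scales$gaussian %||% 3) / min(spacing))) + 1L,
    log = as.integer(ceiling(3 * (scales$log %||% 3) / min(spacing))) + 2L,
    median = as.integer(scales$median %||% 1) + 1L
  )
}
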