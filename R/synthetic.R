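#' Synthetic cohort configuration
#'
#' Defines the statistical structure of a seeded synthetic partial-breast
#' irradiation cohort: cohort size and outcome prevalence, phantom grid
#' geometry, the mix of hypofractionation schemes, and the logistic outcome
#' model on named radiomic features. Defaults emulate the study conditions
#' the package is designed around: 165 patients, 24.8% prevalence and three
#' iso-effective schemes 40 Gy/10, 35 Gy/7 and 28 Gy/4 weighted 73/60/32.
#'
#' @param n_patients Cohort size (>= 10).
#' @param prevalence Expected positive fraction in (0, 1).
#' @param grid_shape Integer voxel triple of the phantom grid.
#' @param voxel_spacing Spacing in mm.
#' @param scheme_mix Data frame with columns `total_dose`, `n_fractions`,
#'   `weight` (weights >= 0, summing to 1).
#' @param effect_coefficients Named numeric vector: logistic slope per
#'   standardized feature (names from [feature_catalog()]).
#' @param hotspot_probability Probability of a Gaussian dose hot spot in the
#'   PTV.
#' @param gland_fraction_range Range of the per-patient glandular fraction
#'   of the breast texture mixture (default `c(0.2, 0.6)`).
#' @param noise_sd_hu Additive HU noise SD.
#' @param alpha_beta Tissue alpha/beta (Gy) used for BED throughout.
#' @param seed Integer master seed.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_patients = 165L,
                          prevalence = 0.248,
                          grid_shape = c(48L, 48L, 32L),
                          voxel_spacing = c(2.5, 2.5, 2.5),
                          scheme_mix = data.frame(
                            total_dose = c(40, 35, 28),
                            n_fractions = c(10L, 7L, 4L),
                            weight = c(73, 60, 32) / 165),
                          effect_coefficients = c(
                            bed_gaussian_ptv_firstorder_p10 = 1.2,
                            red_none_ptv_firstorder_kurtosis = -0.8),
                          hotspot_probability = 0.3,
                          gland_fraction_range = c(0.2, 0.6),
                          noise_sd_hu = 20,
                          alpha_beta = 3,
                          seed = 1L) {
  if (n_patients < 10L) stop("n_patients must be >= 10")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  if (any(grid_shape < 8L)) stop("grid_shape too small")
  if (any(voxel_spacing <= 0)) stop("voxel_spacing must be positive")
  if (any(scheme_mix$weight < 0) || abs(sum(scheme_mix$weight) - 1) > 1e-8) {
    stop("scheme weights must be >= 0 and sum to 1")
  }
  structure(list(n_patients = as.integer(n_patients), prevalence = prevalence,
                 grid_shape = as.integer(grid_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 scheme_mix = scheme_mix,
                 effect_coefficients = effect_coefficients,
                 hotspot_probability = hotspot_probability,
                 gland_fraction_range = gland_fraction_range,
                 noise_sd_hu = noise_sd_hu, alpha_beta = alpha_beta,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate one synthetic patient phantom
#'
#' Builds a half-ellipsoid breast of air-surrounded tissue whose HU texture
#' is a spatially correlated fat/gland mixture (fat ~ -100 HU, gland ~
#' +40 HU, per-patient gland fraction), a spherical PTV placed to respect a
#' 5 mm margin from the breast surface, and a dose grid with a prescription
#' plateau over the PTV, logistic penumbra falloff (5 mm scale) and an
#' optional Gaussian hot spot. Deterministic given `(config$seed, index)`.
#'
#' @param config A [cohort_config()].
#' @param index Patient index in `0..n_patients-1`.
#' @return A `synthetic_patient`: list with `ct`, `dose` ([volume_grid()]s),
#'   `breast_mask`, `ptv_mask` ([roi_mask()]s), `scheme`
#'   ([fractionation_scheme()]), `covariates` (one-row data frame) and
#'   `patient_id`.
#' @export
generate_phantom <- function(config, index) {
  stopifnot(inherits(config, "cohort_config"))
  if (index < 0 || index >= config$n_patients) {
    stop("index must be in 0..n_patients-1")
  }
  local_seed(stage_seed(config$seed, paste0("phantom", index)), {
    d <- config$grid_shape
    sp <- config$voxel_spacing
    ext <- (d - 1) * sp

    # physical coordinates of voxel centers
    xs <- (seq_len(d[1]) - 1) * sp[1]
    ys <- (seq_len(d[2]) - 1) * sp[2]
    zs <- (seq_len(d[3]) - 1) * sp[3]

    # half-ellipsoid breast: chest wall at y = 5 mm, bulging toward +y
    ax <- stats::runif(1, 0.38, 0.46) * ext[1]
    ay <- stats::runif(1, 0.72, 0.85) * ext[2]
    az <- stats::runif(1, 0.38, 0.46) * ext[3]
    cx <- ext[1] / 2; cz <- ext[3] / 2; y0 <- 5
    RX <- outer((xs - cx) / ax, rep(1, d[2]))
    RY <- outer(rep(1, d[1]), (ys - y0) / ay)
    rho2_xy <- RX^2 + RY^2
    breast <- array(FALSE, d)
    for (k in seq_len(d[3])) {
      breast[, , k] <- (rho2_xy + ((zs[k] - cz) / az)^2 <= 1) &
        (RY >= 0)
    }

    # correlated fat/gland texture (correlation length ~6 mm FWHM)
    gfr <- config$gland_fraction_range
    gland_frac <- stats::runif(1, gfr[1], gfr[2])
    noise <- array(stats::rnorm(prod(d)), d)
    sm <- gaussian_3d(noise, 2.5 / sp)
    gland <- if (gland_frac <= 0) {
      array(FALSE, d)
    } else {
      sm > stats::quantile(sm[breast], 1 - gland_frac, names = FALSE)
    }
    hu <- array(-1000, d)
    hu[breast] <- ifelse(gland[breast], 40, -100)
    hu <- hu + array(stats::rnorm(prod(d), 0, config$noise_sd_hu), d) *
      ifelse(breast, 1, 0)

    # spherical PTV respecting a 5 mm margin from the breast surface:
    # the candidate center must be > (radius + 5 mm) from every non-breast
    # voxel center (exact on the grid)
    rp <- stats::runif(1, 10, 16)
    margin <- 5
    sq_dist_to <- function(c3) {
      r2 <- array(0, d)
      for (k in seq_len(d[3])) {
        r2[, , k] <- outer((xs - c3[1])^2, rep(1, d[2])) +
          outer(rep(1, d[1]), (ys - c3[2])^2) + (zs[k] - c3[3])^2
      }
      r2
    }
    ptv_center <- NULL
    r2 <- NULL
    for (try in 1:50) {
      u <- c(stats::runif(1, -0.3, 0.3), stats::runif(1, 0.2, 0.55),
             stats::runif(1, -0.3, 0.3))
      cand <- c(cx + u[1] * ax, y0 + u[2] * ay, cz + u[3] * az)
      cand_r2 <- sq_dist_to(cand)
      if (min(cand_r2[!breast]) >= (rp + margin)^2) {
        ptv_center <- cand
        r2 <- cand_r2
        break
      }
    }
    if (is.null(ptv_center)) {
      stop(sprintf(
        "PTV of radius %.1f mm cannot fit inside the breast with the 5 mm skin margin",
        rp))
    }
    ptv <- r2 <= rp^2 & breast
    if (!any(ptv)) stop("PTV is empty")

    # fractionation scheme drawn from the configured mix
    si <- sample.int(nrow(config$scheme_mix), 1, prob = config$scheme_mix$weight)
    scheme <- fractionation_scheme(config$scheme_mix$total_dose[si],
                                   config$scheme_mix$n_fractions[si],
                                   config$alpha_beta)

    # dose: plateau + logistic penumbra (5 mm scale), optional hot spot
    r <- sqrt(r2)
    dose <- scheme$total_dose * stats::plogis((rp - r) / 5 + 3)
    if (stats::runif(1) < config$hotspot_probability) {
      amp <- stats::runif(1, 0.05, 0.15) * scheme$total_dose
      hs_sd <- stats::runif(1, 4, 8)
      hs_dir <- stats::rnorm(3); hs_dir <- hs_dir / sqrt(sum(hs_dir^2))
      hs_c <- ptv_center + hs_dir * stats::runif(1, 0, rp / 2)
      hr2 <- array(0, d)
      for (k in seq_len(d[3])) {
        hr2[, , k] <- outer((xs - hs_c[1])^2, rep(1, d[2])) +
          outer(rep(1, d[1]), (ys - hs_c[2])^2) + (zs[k] - hs_c[3])^2
      }
      dose <- dose + amp * exp(-hr2 / (2 * hs_sd^2))
    }

    covariates <- data.frame(
      age = round(min(max(stats::rnorm(1, 70, 6), 50), 90), 1),
      comorbidity = stats::rbinom(1, 1, 0.32),
      histology = sample(c("ductal", "lobular"), 1, prob = c(0.94, 0.06)),
      laterality = sample(c("left", "right"), 1, prob = c(0.44, 0.56)),
      quadrant = sample(c("upper_outer", "upper_inner", "lower_outer",
                          "lower_inner", "central"), 1,
                        prob = c(0.485, 0.194, 0.091, 0.139, 0.091)),
      tumor_size_mm = round(max(stats::rnorm(1, 12, 5), 2), 1),
      chemotherapy = stats::rbinom(1, 1, 0.08),
      hormone_therapy = stats::rbinom(1, 1, 0.69),
      followup_months = round(min(max(stats::rnorm(1, 60, 15), 18), 85), 1)
    )

    structure(list(
      patient_id = sprintf("pt_%04d", index),
      ct = volume_grid(hu, sp),
      dose = volume_grid(dose, sp),
      breast_mask = roi_mask(breast, sp, roi_name = "breast"),
      ptv_mask = roi_mask(ptv, sp, roi_name = "ptv"),
      scheme = scheme,
      covariates = covariates
    ), class = "synthetic_patient")
  })
}

# resolve feature names against the catalog; error lists valid names
resolve_features <- function(names_, catalog = feature_catalog()) {
  unknown <- setdiff(names_, catalog$name)
  if (length(unknown) > 0) {
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "),
         "; valid names are the `name` column of feature_catalog()")
  }
  catalog[catalog$name %in% names_, , drop = FALSE]
}

#' Compute a subset of catalog features for one synthetic patient
#'
#' Runs the standard preprocessing chain (resample to the target grid,
#' HU to RED, dose to BED) and extracts only the requested catalog columns.
#'
#' @param patient A `synthetic_patient` from [generate_phantom()].
#' @param feature_names Character vector of catalog column names.
#' @param target_spacing Analysis grid spacing in mm (default 3).
#' @param curve HU-RED calibration (default [default_calibration()]).
#' @return Named numeric vector.
#' @export
compute_patient_features <- function(patient, feature_names,
                                     target_spacing = c(3, 3, 3),
                                     curve = default_calibration()) {
  cat_sub <- resolve_features(feature_names)
  ct <- resample(patient$ct, target_spacing)
  red <- hu_to_red(ct, curve)
  bed <- dose_to_bed(resample(patient$dose, target_spacing), patient$scheme)
  breast <- resample(patient$breast_mask, target_spacing)
  ptv <- resample(patient$ptv_mask, target_spacing)
  extract_all(red, bed, breast, ptv, catalog = cat_sub)[feature_names]
}

#' Assign outcomes to a synthetic cohort
#'
#' Labels follow `Bernoulli(plogis(intercept + sum coef * z))` where `z` are
#' the cohort-standardized planted features named in
#' `config$effect_coefficients`; the intercept is calibrated so the expected
#' cohort prevalence equals `config$prevalence`.
#'
#' @param features Data frame (or matrix) of patient features containing at
#'   least the columns named in `config$effect_coefficients`.
#' @param config A [cohort_config()].
#' @return List with `label` (integer 0/1), `latent_score` (linear
#'   predictor) and `intercept`.
#' @export
assign_outcome <- function(features, config) {
  stopifnot(inherits(config, "cohort_config"))
  coefs <- config$effect_coefficients
  eta <- rep(0, nrow(features))
  if (length(coefs) > 0) {
    resolve_features(names(coefs))  # validates names
    missing_cols <- setdiff(names(coefs), colnames(features))
    if (length(missing_cols) > 0) {
      stop("features table lacks planted columns: ",
           paste(missing_cols, collapse = ", "))
    }
    for (nm in names(coefs)) {
      x <- features[[nm]]
      s <- stats::sd(x)
      z <- if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
      eta <- eta + coefs[[nm]] * z
    }
  }
  # calibrate the intercept so that mean risk == prevalence
  f <- function(b0) mean(stats::plogis(b0 + eta)) - config$prevalence
  b0 <- stats::uniroot(f, c(-30, 30))$root
  p <- stats::plogis(b0 + eta)
  label <- local_seed(stage_seed(config$seed, "outcome"),
                      stats::rbinom(length(p), 1, p))
  list(label = as.integer(label), latent_score = b0 + eta, intercept = b0)
}

#' Generate and write a full synthetic cohort
#'
#' Generates `n_patients` phantoms, assigns outcomes from the configured
#' logistic model, writes each patient's CT, dose and mask volumes as NIfTI
#' files plus a cohort CSV (covariates, scheme, label), and returns the
#' manifest. Idempotent for a fixed seed.
#'
#' @param config A [cohort_config()].
#' @param out_dir Writable output directory (created if needed).
#' @return Manifest data frame (one row per patient), invisibly also written
#'   to `cohort.csv`.
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  patients <- lapply(seq_len(config$n_patients) - 1L,
                     function(i) generate_phantom(config, i))
  eff_names <- names(config$effect_coefficients)
  feat <- if (length(eff_names) > 0) {
    do.call(rbind, lapply(patients, function(p) {
      as.data.frame(t(compute_patient_features(p, eff_names)))
    }))
  } else {
    data.frame(row.names = seq_along(patients))
  }
  outc <- assign_outcome(feat, config)

  rows <- vector("list", length(patients))
  for (i in seq_along(patients)) {
    p <- patients[[i]]
    paths <- file.path(out_dir, paste0(p$patient_id, "_",
                                       c("ct", "dose", "breast", "ptv"),
                                       ".nii.gz"))
    write_volume(p$ct, paths[1])
    write_volume(p$dose, paths[2])
    write_volume(p$breast_mask, paths[3])
    write_volume(p$ptv_mask, paths[4])
    rows[[i]] <- cbind(
      data.frame(patient_id = p$patient_id, ct_path = basename(paths[1]),
                 dose_path = basename(paths[2]),
                 breast_path = basename(paths[3]),
                 ptv_path = basename(paths[4]),
                 total_dose_gy = p$scheme$total_dose,
                 n_fractions = p$scheme$n_fractions,
                 label = outc$label[i],
                 latent_score = outc$latent_score[i]),
      p$covariates)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  manifest
}

#' Generate a class-conditional Gaussian feature table
#'
#' Fast fixture for the augmentation/selection/training stages: positives are
#' shifted by `shift` on the first `length(shift)` features, the remaining
#' features are pure noise. Column names are taken from the radiomics
#' catalog so tables look like real extractor output.
#'
#' @param n_pos,n_neg Class sizes.
#' @param n_features Total feature count (>= `length(shift)`).
#' @param shift Numeric vector of positive-class mean shifts (in SD units).
#' @param seed Integer seed.
#' @return Data frame with `patient_id`, `label` and `n_features` numeric
#'   columns.
#' @export
generate_feature_table <- function(n_pos, n_neg, n_features = 20L,
                                   shift = c(1, 1), seed = 1L) {
  if (n_features < length(shift)) stop("n_features must be >= length(shift)")
  catalog <- feature_catalog()
  nm <- catalog$name[catalog$family != "shape"][seq_len(n_features)]
  local_seed(seed, {
    n <- n_pos + n_neg
    lab <- c(rep(1L, n_pos), rep(0L, n_neg))
    X <- matrix(stats::rnorm(n * n_features), n, n_features)
    for (j in seq_along(shift)) {
      X[lab == 1L, j] <- X[lab == 1L, j] + shift[j]
    }
    colnames(X) <- nm
    out <- cbind(data.frame(patient_id = sprintf("pt_%04d", seq_len(n) - 1L),
                            label = lab), as.data.frame(X))
    # shuffle rows so folds are not ordered by class
    out <- out[sample.int(n), ]
    rownames(out) <- NULL
    out
  })
}

#' Generate a feature-table-level synthetic cohort
#'
#' Draws standard-normal radiomics-named features and assigns outcomes via
#' the configured logistic model — the feature-space counterpart of
#' [generate_cohort()] for experiments where image-level phantoms are not
#' needed (selection/evaluation studies).
#'
#' @param config A [cohort_config()]; `effect_coefficients` name the planted
#'   columns.
#' @param n_noise Number of additional pure-noise feature columns.
#' @return Data frame with `patient_id`, `label`, `latent_score` and feature
#'   columns.
#' @export
generate_cohort_features <- function(config, n_noise = 28L) {
  stopifnot(inherits(config, "cohort_config"))
  coefs <- config$effect_coefficients
  resolve_features(names(coefs))
  catalog <- feature_catalog()
  noise_nm <- setdiff(catalog$name[catalog$family != "shape"], names(coefs))
  noise_nm <- noise_nm[seq_len(n_noise)]
  n <- config$n_patients
  X <- local_seed(stage_seed(config$seed, "cohort_features"), {
    m <- matrix(stats::rnorm(n * (length(coefs) + n_noise)), nrow = n)
    colnames(m) <- c(names(coefs), noise_nm)
    m
  })
  df <- as.data.frame(X)
  outc <- assign_outcome(df, config)
  cbind(data.frame(patient_id = sprintf("pt_%04d", seq_len(n) - 1L),
                   label = outc$label, latent_score = outc$latent_score), df)
}
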