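#' ADASYN parameters
#'
#' @param k Neighbour count for the density estimate and interpolation pool
#'   (default 5, the canonical choice).
#' @param beta Balance level in `[0, 1]`; 1 (default) removes the imbalance
#'   completely.
#' @param seed Integer seed for the synthesis RNG.
#' @return An `adasyn_params` object.
#' @export
adasyn_params <- function(k = 5L, beta = 1, seed = 1L) {
  if (!is.numeric(k) || k < 1) stop("k must be >= 1")
  if (!is.numeric(beta) || beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  structure(list(k = as.integer(k), beta = beta, seed = as.integer(seed)),
            class = "adasyn_params")
}

#' ADASYN oversampling of the minority class
#'
#' Adaptive synthetic sampling: the number of synthetic points to generate,
#' `G = beta * (n_maj - n_min)`, is allocated across minority instances
#' proportionally to the fraction `r_i = Delta_i / k` of majority points
#' among each instance's k nearest neighbours (all classes), so
#' hard-to-learn minority points near the class boundary are oversampled
#' most. Each synthetic point is a convex combination
#' `x_i + lambda * (x_z - x_i)`, `lambda ~ U(0, 1)`, of a minority instance
#' and one of its k nearest *minority* neighbours. Distances are Euclidean on
#' z-scored features (radiomics features span wildly different scales);
#' synthesis happens in original units.
#'
#' @param table Data frame with a binary `label` column (0/1; 1 = minority
#'   assumed, checked) and numeric feature columns. Non-feature metadata
#'   columns `patient_id` and `is_synthetic` are carried through.
#' @param params An [adasyn_params()].
#' @return The input table with synthetic minority rows appended and an
#'   `is_synthetic` logical column.
#' @export
adasyn <- function(table, params = adasyn_params()) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  lab <- as.integer(table$label)
  if (!all(lab %in% 0:1)) stop("label must be binary 0/1")
  if (length(unique(lab)) < 2L) stop("both classes must be present")
  feat_cols <- feature_columns(table)
  X <- as.matrix(table[, feat_cols, drop = FALSE])
  if (!is.numeric(X)) stop("feature columns must be numeric")

  counts <- table(factor(lab, levels = 0:1))
  minority <- as.integer(names(which.min(counts)))
  n_min <- min(counts); n_maj <- max(counts)
  if (n_min < params$k + 1L) stop("minority class needs >= k + 1 members")

  G <- params$beta * (n_maj - n_min)
  out <- table
  out$is_synthetic <- out$is_synthetic %||% rep(FALSE, nrow(table))
  if (round_half_up(G) == 0) return(out)

  mu <- colMeans(X); sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sd_, `/`)
  D <- as.matrix(stats::dist(Z))
  diag(D) <- Inf

  min_idx <- which(lab == minority)
  k <- params$k
  # Delta_i: majority members among the k nearest neighbours over all classes
  delta <- vapply(min_idx, function(i) {
    nn <- order(D[i, ])[seq_len(k)]
    sum(lab[nn] != minority)
  }, 0L)
  r <- delta / k
  if (sum(r) == 0) {
    warning("no minority point has majority neighbours; uniform allocation used")
    g <- rep(round_half_up(G / n_min), n_min)
  } else {
    g <- round_half_up(r / sum(r) * G)
  }

  # interpolation partners: k nearest minority neighbours
  Dmin <- D[min_idx, min_idx, drop = FALSE]
  syn <- local_seed(params$seed, {
    rows <- vector("list", length(min_idx))
    for (u in seq_along(min_idx)) {
      if (g[u] == 0) next
      pool <- order(Dmin[u, ])[seq_len(min(k, length(min_idx) - 1L))]
      zpick <- pool[sample.int(length(pool), g[u], replace = TRUE)]
      lambda <- stats::runif(g[u])
      Xi <- matrix(X[min_idx[u], ], nrow = g[u], ncol = ncol(X), byrow = TRUE)
      Xz <- X[min_idx[zpick], , drop = FALSE]
      rows[[u]] <- Xi + lambda * (Xz - Xi)
    }
    do.call(rbind, rows)
  })
  if (is.null(syn) || nrow(syn) == 0) return(out)

  new_rows <- table[rep(min_idx[1], nrow(syn)), , drop = FALSE]
  new_rows[, feat_cols] <- syn
  new_rows$label <- minority
  if ("patient_id" %in% names(new_rows)) {
    new_rows$patient_id <- sprintf("syn_%04d", seq_len(nrow(syn)))
  }
  new_rows$is_synthetic <- TRUE
  rownames(new_rows) <- NULL
  out <- rbind(out, new_rows)
  rownames(out) <- NULL
  out
}

# numeric feature columns: everything except metadata
feature_columns <- function(table) {
  meta <- c("patient_id", "label", "is_synthetic", "latent_score")
  nm <- setdiff(names(table), meta)
  nm[vapply(table[nm], is.numeric, TRUE)]
}

#' Check an ADASYN augmentation against its input
#'
#' Verifies the original rows are unchanged, reports class counts, whether
#' every synthetic row lies inside the per-feature bounding box of the
#' minority class (a necessary consequence of convex-combination synthesis),
#' and the distance from each synthetic row to its nearest original row.
#'
#' @param original The table passed to [adasyn()].
#' @param augmented Its return value.
#' @return List with `counts`, `n_synthetic`, `range_contained`,
#'   `nearest_original_distance`.
#' @export
verify_augmentation <- function(original, augmented) {
  feat_cols <- feature_columns(original)
  n0 <- nrow(original)
  orig_part <- augmented[seq_len(n0), names(original), drop = FALSE]
  rownames(orig_part) <- rownames(original)
  if (!isTRUE(all.equal(orig_part, original, check.attributes = FALSE))) {
    stop("original rows were mutated by augmentation")
  }
  syn <- augmented[augmented$is_synthetic %||% rep(FALSE, nrow(augmented)), ,
                   drop = FALSE]
  lab <- as.integer(original$label)
  minority <- as.integer(names(which.min(table(factor(lab, levels = 0:1)))))
  Xmin <- as.matrix(original[lab == minority, feat_cols, drop = FALSE])
  contained <- TRUE
  nearest <- numeric(0)
  if (nrow(syn) > 0) {
    Xs <- as.matrix(syn[, feat_cols, drop = FALSE])
    lo <- apply(Xmin, 2, min); hi <- apply(Xmin, 2, max)
    contained <- all(t(Xs) >= lo - 1e-9) && all(t(Xs) <= hi + 1e-9)
    X0 <- as.matrix(original[, feat_cols, drop = FALSE])
    nearest <- vapply(seq_len(nrow(Xs)), function(i) {
      sqrt(min(colSums((t(X0) - Xs[i, ])^2)))
    }, 0)
  }
  list(
    counts = table(augmented$label),
    n_synthetic = nrow(syn),
    minority_fraction = mean(as.integer(augmented$label) == minority),
    range_contained = contained,
    nearest_original_distance = nearest
  )
}
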