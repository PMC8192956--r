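#' Principal component analysis of a spectral region
#'
#' Each specimen's region is vector-normalized (unit Euclidean norm), column
#' means are subtracted, and components are obtained by singular-value
#' decomposition ([stats::prcomp()], no variance scaling: absorbance is a
#' single modality and SD-scaling would distort the loadings). Sign
#' convention: each loading is flipped so that its largest-magnitude entry is
#' positive, making scores reproducible across platforms.
#'
#' @param set A [spectrum_set()] on a common grid covering `region`.
#' @param region `c(lo, hi)` in cm^-1.
#' @param n_components Number of components to retain; defaults to the
#'   maximum, `min(n_specimens - 1, n_points)`.
#' @return A `pca_result`: `scores` (specimens x components), `loadings`
#'   (components x wavenumbers), `explained_fraction`, `grid`,
#'   `centering_mean`, `meta` (specimen metadata tibble).
#' @export
fit_pca <- function(set, region, n_components = NULL) {
  stopifnot(inherits(set, "spectrum_set"))
  if (length(set$spectra) < 2L) {
    vs_abort("PCA needs at least 2 specimens", "valvespectra_size_error")
  }
  X <- region_matrix(set, region, normalize = TRUE)
  grid <- as.numeric(colnames(X))
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (is.null(n_components)) n_components <- kmax
  if (n_components > kmax) {
    vs_abort(sprintf("n_components must be <= min(n_specimens - 1, n_points) = %d", kmax),
             "valvespectra_size_error")
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  k <- n_components
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- t(pc$rotation[, seq_len(k), drop = FALSE])
  # sign convention: largest-|.| entry of each loading positive
  for (i in seq_len(k)) {
    j <- which.max(abs(loadings[i, ]))
    if (loadings[i, j] < 0) {
      loadings[i, ] <- -loadings[i, ]
      scores[, i] <- -scores[, i]
    }
  }
  ev <- pc$sdev^2
  structure(list(
    scores = scores,
    loadings = loadings,
    explained_fraction = (ev / sum(ev))[seq_len(k)],
    grid = grid,
    centering_mean = pc$center,
    meta = set_metadata(set)
  ), class = "pca_result")
}

# specimens x wavenumbers matrix for a region, optionally row-normalized
region_matrix <- function(set, region, normalize = TRUE) {
  rows <- lapply(set$spectra, function(s) {
    r <- extract_region(s, region[1], region[2])
    v <- if (normalize) vector_normalize(r$absorbance) else r$absorbance
    setNames(v, r$wavenumbers)
  })
  npts <- unique(lengths(rows))
  if (length(npts) != 1L) {
    vs_abort("specimens do not share a common grid over the region",
             "valvespectra_grid_error")
  }
  X <- do.call(rbind, rows)
  X
}

#' Project new spectra onto a fitted PCA
#'
#' Applies the same vector normalization and centering as [fit_pca()], then
#' projects onto the stored loadings.
#'
#' @param pca A `pca_result`.
#' @param set A [spectrum_set()] covering the PCA's grid.
#' @return Scores matrix (specimens x components).
#' @export
project_pca <- function(pca, set) {
  stopifnot(inherits(pca, "pca_result"))
  region <- range(pca$grid)
  X <- region_matrix(set, region, normalize = TRUE)
  sweep(X, 2, pca$centering_mean) %*% t(pca$loadings)
}

#' Number of principal components for downstream LDA
#'
#' The smallest k whose cumulative explained-variance fraction reaches
#' `target`, capped at `n_specimens - n_classes` so the pooled within-class
#' covariance stays estimable.
#'
#' @param pca A `pca_result`.
#' @param n_classes Number of classes the LDA will see.
#' @param target Cumulative explained-variance target. Default 0.99.
#' @return Integer >= 1.
#' @export
choose_n_pcs <- function(pca, n_classes, target = 0.99) {
  k <- which(cumsum(pca$explained_fraction) >= target)[1]
  if (is.na(k)) k <- length(pca$explained_fraction)
  cap <- nrow(pca$scores) - n_classes
  max(1L, min(k, cap))
}

#' Linear discriminant analysis on PC scores
#'
#' Pooled within-class covariance Gaussian classifier with equal
#' misclassification costs: class means and a shared covariance are estimated
#' in the space of the first `n_pcs` principal-component scores, and
#' prediction maximizes the linear discriminant score
#' `x' S^-1 m_k - m_k' S^-1 m_k / 2 + log p_k`. A singular pooled covariance
#' falls back to a ridge (`1e-8 * trace`) with a warning. Prediction ties are
#' broken by class order.
#'
#' @param pca A `pca_result` (or a plain scores matrix).
#' @param labels Class label per specimen.
#' @param n_pcs Number of leading PCs to use; defaults to [choose_n_pcs()].
#' @return An `lda_model`: `n_pcs_used`, `class_order`, `class_means`,
#'   `shared_covariance`, `priors`.
#' @export
fit_lda <- function(pca, labels, n_pcs = NULL) {
  scores <- if (inherits(pca, "pca_result")) pca$scores else as.matrix(pca)
  lev <- if (all(unique(as.character(labels)) %in% treatment_levels())) {
    intersect(treatment_levels(), unique(as.character(labels)))
  } else unique(as.character(labels))
  y <- factor(as.character(labels), levels = lev)
  if (is.null(n_pcs) && inherits(pca, "pca_result")) {
    n_pcs <- choose_n_pcs(pca, nlevels(y))
  }
  if (is.null(n_pcs) || n_pcs < 1L) {
    vs_abort("n_pcs must be >= 1", "valvespectra_precondition_error")
  }
  if (any(table(y) < 2L)) {
    vs_abort("every class needs >= 2 specimens", "valvespectra_precondition_error")
  }
  n_pcs <- min(as.integer(n_pcs), ncol(scores))
  Z <- scores[, seq_len(n_pcs), drop = FALSE]
  mus <- t(vapply(lev, function(cl) colMeans(Z[y == cl, , drop = FALSE]),
                  numeric(n_pcs)))
  n <- nrow(Z)
  K <- nlevels(y)
  S <- matrix(0, n_pcs, n_pcs)
  for (cl in lev) {
    Zi <- Z[y == cl, , drop = FALSE]
    D <- sweep(Zi, 2, colMeans(Zi))
    S <- S + crossprod(D)
  }
  S <- S / (n - K)
  inv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(inv) || rcond(S) < 1e-12) {
    vs_warn("singular pooled covariance; applying ridge regularization",
            "valvespectra_singular_covariance_warning")
    S <- S + diag(1e-8 * sum(diag(S)), n_pcs)
    inv <- solve(S)
  }
  structure(list(n_pcs_used = n_pcs, class_order = lev, class_means = mus,
                 shared_covariance = S, cov_inverse = inv,
                 priors = as.numeric(table(y)) / n),
            class = "lda_model")
}

#' @param object An `lda_model`.
#' @param newdata Scores matrix (specimens x >= n_pcs_used columns).
#' @param ... Unused.
#' @return List with `class` (character) and `scores` (discriminant values).
#' @rdname fit_lda
#' @export
predict.lda_model <- function(object, newdata, ...) {
  Z <- as.matrix(newdata)[, seq_len(object$n_pcs_used), drop = FALSE]
  A <- object$cov_inverse %*% t(object$class_means)            # p x K
  const <- -0.5 * colSums(t(object$class_means) * A) + log(object$priors)
  disc <- sweep(Z %*% A, 2, const, `+`)
  colnames(disc) <- object$class_order
  idx <- apply(disc, 1, which.max)  # first max = class-order tie-break
  list(class = object$class_order[idx], scores = disc)
}

#' Leave-one-out cross-validated PCA + LDA classification
#'
#' For each specimen, PCA and LDA are refit on the remaining specimens (no
#' leakage of the held-out spectrum into normalization, centering, or the
#' discriminant) and the held-out spectrum is projected and classified.
#'
#' @param set A [spectrum_set()] with metadata.
#' @param labels Class label per specimen; defaults to the treatments.
#' @param region Spectral region, default the 1800-900 cm^-1 fingerprint.
#' @param n_pcs Number of PCs; `NULL` re-chooses per fold via [choose_n_pcs()].
#' @return A `loocv_result` (see [run_loocv()]) with `$predictions` and
#'   `$confusion`.
#' @export
lda_loocv <- function(set, labels = NULL, region = c(900, 1800), n_pcs = NULL) {
  stopifnot(inherits(set, "spectrum_set"))
  if (is.null(labels)) labels <- set_metadata(set)$treatment
  labels <- as.character(labels)
  n <- length(set$spectra)
  lev <- if (all(unique(labels) %in% treatment_levels())) {
    intersect(treatment_levels(), unique(labels))
  } else unique(labels)
  pred <- character(n)
  for (i in seq_len(n)) {
    train <- spectrum_set(set$spectra[-i])
    pca <- fit_pca(train, region)
    mod <- fit_lda(pca, labels[-i], n_pcs = n_pcs)
    z <- project_pca(pca, spectrum_set(set$spectra[i]))
    pred[i] <- predict(mod, z)$class
  }
  loocv_result(truth = labels, predicted = pred, class_order = lev,
               probabilities = NULL, fold_seeds = NULL,
               classifier = "pca_lda")
}
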