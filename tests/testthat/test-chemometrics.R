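make_rank2_set <- function(n = 8, grid = seq(900, 1800, by = 2)) {
  base <- gauss(grid, 1650, 20, 1) + gauss(grid, 1100, 40, 0.5)
  second <- gauss(grid, 1400, 30, 1)
  specs <- lapply(seq_len(n), function(i) {
    ftir_spectrum(grid, (1 + 0.05 * i) * base + 0.02 * i^2 * second,
                  meta = specimen_meta(sprintf("V%02d", i), "leaflet", "control"))
  })
  spectrum_set(specs, common_grid = grid)
}

test_that("PCA explains rank-2 data with two components and sorts fractions", {
  p <- fit_pca(make_rank2_set(), c(900, 1800))
  expect_equal(sum(p$explained_fraction[1:2]), 1, tolerance = 1e-10)
  expect_true(all(diff(p$explained_fraction) <= 1e-12))
  expect_true(all(p$explained_fraction >= 0 & p$explained_fraction <= 1))
  expect_error(fit_pca(spectrum_set(make_rank2_set()$spectra[1]), c(900, 1800)),
               class = "valvespectra_size_error")
})

test_that("PCA loadings are orthonormal and reconstruction reproduces the centered data", {
  set <- generate_dataset(n_per_group = 3,
                          treatments = c("control", "H2O2", "FeCl3"), seed = 9)
  p <- fit_pca(set, c(900, 1800))
  G <- p$loadings %*% t(p$loadings)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-8)
  X <- valvespectra:::region_matrix(set, c(900, 1800), normalize = TRUE)
  Xhat <- p$scores %*% p$loadings + matrix(p$centering_mean, nrow(X),
                                           ncol(X), byrow = TRUE)
  expect_lt(max(abs(X - Xhat)), 1e-8)
  # sign convention: largest-magnitude loading entry positive
  for (i in seq_len(nrow(p$loadings))) {
    expect_gt(p$loadings[i, which.max(abs(p$loadings[i, ]))], 0)
  }
})

test_that("PCA scores are invariant under specimen reordering", {
  set <- generate_dataset(n_per_group = 2,
                          treatments = c("control", "H2O2"), seed = 21)
  p1 <- fit_pca(set, c(900, 1800))
  perm <- c(3, 1, 4, 2)
  p2 <- fit_pca(spectrum_set(set$spectra[perm], common_grid = set$common_grid),
                c(900, 1800))
  expect_equal(p2$scores[, 1:2], p1$scores[perm, 1:2], tolerance = 1e-9)
})

test_that("projection of the training set reproduces its own scores", {
  set <- make_rank2_set()
  p <- fit_pca(set, c(900, 1800))
  z <- project_pca(p, set)
  expect_equal(unname(z), unname(p$scores), tolerance = 1e-9)
})

test_that("FeCl3-type damage separates along PC1 while null groups overlap", {
  eff <- default_group_effects()
  eff$H2O2 <- group_effect("H2O2")  # only the FeCl3 effect is active
  hits <- 0
  for (k in 1:10) {
    set <- generate_dataset(seed = 400 + k, effects = eff)
    p <- fit_pca(set, c(900, 1800), n_components = 2)
    lab <- set_metadata(set)$treatment
    s1 <- p$scores[, 1]
    fe <- range(s1[lab == "FeCl3"]); rest <- range(s1[lab != "FeCl3"])
    if (fe[1] > rest[2] || fe[2] < rest[1]) hits <- hits + 1
  }
  expect_gte(hits, 9)

  # identically distributed storage/control groups stay mixed: silhouette
  # of the treatment labels in PC1-2 space is near zero
  set <- generate_dataset(seed = 5, treatments = c("control", "freeze_dried",
                                                   "stored_4C"))
  p <- fit_pca(set, c(900, 1800), n_components = 2)
  lab <- set_metadata(set)$treatment
  D <- as.matrix(dist(p$scores[, 1:2]))
  sil <- vapply(seq_along(lab), function(i) {
    a <- mean(D[i, lab == lab[i] & seq_along(lab) != i])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(g) mean(D[i, lab == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_lt(mean(sil), 0.2)
})

test_that("LDA attains perfect resubstitution on well-separated classes and breaks ties by order", {
  set.seed(6)
  z <- rbind(matrix(rnorm(12, 0, 0.5), 6, 2),
             matrix(rnorm(12, 10, 0.5), 6, 2))
  labels <- rep(c("A", "B"), each = 6)
  mod <- fit_lda(z, labels, n_pcs = 2)
  expect_equal(predict(mod, z)$class, labels)
  expect_equal(sum(mod$priors), 1)
  expect_error(fit_lda(z, labels, n_pcs = 0),
               class = "valvespectra_precondition_error")
  expect_error(fit_lda(z[c(1, 7:12), ], labels[c(1, 7:12)], n_pcs = 2),
               class = "valvespectra_precondition_error")
  # singular pooled covariance falls back to a ridge with a warning
  zs <- cbind(z[, 1], z[, 1])
  expect_warning(mods <- fit_lda(zs, labels, n_pcs = 2),
                 class = "valvespectra_singular_covariance_warning")
  expect_equal(predict(mods, zs)$class, labels)
})

test_that("LDA predictions agree with the MASS reference on a generic problem", {
  skip_if_not_installed("MASS")
  set.seed(8)
  z <- rbind(matrix(rnorm(30, 0, 1), 15, 2),
             matrix(rnorm(30, 1.2, 1), 15, 2))
  labels <- rep(c("A", "B"), each = 15)
  ours <- predict(fit_lda(z, labels, n_pcs = 2), z)$class
  ref <- as.character(predict(MASS::lda(z, grouping = labels))$class)
  expect_gt(mean(ours == ref), 0.96)
})

test_that("label permutation drives LDA LOOCV to chance", {
  set.seed(14)
  z <- matrix(rnorm(48), 24, 2)
  labels <- rep(c("A", "B"), each = 12)
  acc <- replicate(200, {
    lab_p <- sample(labels)
    hits <- vapply(seq_len(nrow(z)), function(i) {
      mod <- fit_lda(z[-i, ], lab_p[-i], n_pcs = 2)
      predict(mod, z[i, , drop = FALSE])$class == lab_p[i]
    }, logical(1))
    mean(hits)
  })
  # no optimistic leak above chance; LOOCV at the null carries the known
  # pessimistic bias (the held-out class is underrepresented in training),
  # so the mean sits slightly below 1/2
  expect_lt(mean(acc), 0.55)
  expect_gt(mean(acc), 0.30)
})

test_that("PC count selection honors the variance target and the class cap", {
  p <- fit_pca(make_rank2_set(), c(900, 1800))  # exactly rank 2 when centered
  expect_equal(choose_n_pcs(p, n_classes = 2, target = 0.5), 1)
  expect_equal(choose_n_pcs(p, n_classes = 2, target = 1 - 1e-12), 2)
  expect_equal(choose_n_pcs(p, n_classes = 7, target = 1 - 1e-12), 1)  # cap >= 1
})

test_that("cross-validated PCA+LDA classifies oxidative damage in the full design", {
  set <- generate_dataset(seed = 42)
  res <- lda_loocv(set)
  cm <- res$confusion
  expect_equal(sum(cm), 36)
  expect_equal(cm["FeCl3", "FeCl3"], 6L)
  expect_gte(cm["H2O2", "H2O2"], 5L)
  expect_equal(nrow(res$predictions), 36)
})
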