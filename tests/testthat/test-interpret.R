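test_that("PCA projections report explained variance and ignore ordering", {
  set.seed(7)
  # points exactly on a 2-D plane embedded in 6 dimensions
  basis <- qr.Q(qr(matrix(rnorm(12), 6)))[, 1:2]
  X <- matrix(rnorm(40), 20) %*% t(basis)
  rownames(X) <- paste0("s", 1:20)
  emb <- project(X, "pca")
  expect_s3_class(emb, "embedding2d")
  expect_equal(sum(attr(emb, "explained_variance")), 1, tolerance = 1e-10)

  perm <- sample(20)
  emb2 <- project(X[perm, ], "pca")
  agree <- sapply(c("x", "y"), function(cc)
    min(max(abs(emb2[[cc]] - emb[[cc]][perm])),
        max(abs(emb2[[cc]] + emb[[cc]][perm]))))
  expect_lt(max(agree), 1e-8)           # identical up to sign per axis
  expect_error(project(X[1:2, ], "pca"), "at least 3")
})

test_that("t-SNE separates well-separated clusters and is seed-stable", {
  set.seed(30)
  X <- rbind(matrix(rnorm(45 * 8), 45), matrix(rnorm(45 * 8, mean = 8), 45))
  emb <- project(X, "tsne", seed = 3, n_iter = 300)
  km <- kmeans(cbind(emb$x, emb$y), 2, nstart = 5)
  lab <- rep(1:2, each = 45)
  agree <- max(mean(km$cluster == lab), mean(km$cluster == 3 - lab))
  expect_gte(agree, 0.95)
  emb2 <- project(X, "tsne", seed = 3, n_iter = 300)
  expect_identical(emb$x, emb2$x)
})

test_that("Shapley attributions localise dependence and stay additive", {
  co <- small_cohort(n = 20, n_points = 50, seed = 12)
  explained <- subset_samples(co$spectra, co$spectra$sample_ids[1:8])
  bg <- subset_samples(co$spectra, co$spectra$sample_ids[21:35])

  # model depending on wavelength 17 only
  f <- function(M) M[, 17] / max(co$spectra$values)
  imp <- shap_wavelength_importance(f, explained, bg, seed = 2, n_perm = 6)
  expect_equal(which.max(imp$importance), 17L)
  expect_true(all(imp$importance >= 0))
  # per-sample additivity: attributions sum to f(x) minus the mean output of
  # the backgrounds drawn for that sample
  expect_equal(rowSums(imp$attributions),
               imp$predicted_values - imp$reference_values,
               tolerance = 1e-10, ignore_attr = TRUE)
  # deterministic given the seed
  imp2 <- shap_wavelength_importance(f, explained, bg, seed = 2, n_perm = 6)
  expect_identical(imp$attributions, imp2$attributions)

  # constant model -> all importances zero
  imp0 <- shap_wavelength_importance(function(M) rep(0.5, nrow(M)),
                                     explained, bg, seed = 1, n_perm = 3)
  expect_equal(max(imp0$importance), 0)

  wrong_grid <- spectrum_set(1:10, matrix(1:20 + 0.5, 10),
                             sample_ids = c("a", "b"))
  expect_error(shap_wavelength_importance(f, explained, wrong_grid), "grids")
})

test_that("Shapley importance works on a trained 1-D network", {
  co <- generate_cohort(synthetic_config(n_per_class = c(15, 15),
                                         n_points = 32, rng_seed = 3))
  m <- fit_baseline("cnn1d", co$spectra, co$labels, seed = 1,
                    tc = train_config(epochs = 10L, rng_seed = 1))
  sub <- subset_samples(co$spectra, co$spectra$sample_ids[c(1, 16)])
  bg <- subset_samples(co$spectra, co$spectra$sample_ids[5:14])
  imp <- shap_wavelength_importance(m, sub, bg, seed = 4, n_perm = 3)
  expect_length(imp$importance, 32L)
  expect_equal(rowSums(imp$attributions),
               imp$predicted_values - imp$reference_values,
               tolerance = 1e-10, ignore_attr = TRUE)
})
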