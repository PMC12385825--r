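test_that("SIMPLS matches the reference PLS implementation", {
  set.seed(9)
  X <- matrix(rnorm(40 * 15), 40, dimnames = list(NULL, paste0("V", 1:15)))
  y <- rnorm(40)
  fit <- simpls_fit(X, y, 4)
  mo <- mixOmics::pls(X, y, ncomp = 4, mode = "regression", scale = FALSE)
  pr_ref <- predict(mo, X)$predict[, 1, 4]
  expect_equal(unname(predict(fit, X, ncomp = 4)), unname(pr_ref),
               tolerance = 1e-10)
})

test_that("SIMPLS with one component reduces to a latent-score threshold", {
  # one informative direction: the single-component prediction is an affine
  # function of the projection onto X'y, checked against the closed form
  set.seed(2)
  X <- matrix(rnorm(30 * 8), 30)
  y <- rnorm(30)
  fit <- simpls_fit(X, y, 1)
  Xc <- scale(X, scale = FALSE)
  s <- crossprod(Xc, y - mean(y))
  t1 <- Xc %*% s
  beta <- sum((y - mean(y)) * t1) / sum(t1^2)
  expect_equal(unname(predict(fit, X, ncomp = 1)),
               unname(mean(y) + beta * t1[, 1]), tolerance = 1e-10)
})

test_that("CARS follows its retention schedule and selects the RMSECV argmin", {
  co <- generate_cohort(synthetic_config(n_per_class = c(30, 30),
                                         n_points = 120, rng_seed = 4))
  cfg <- cars_config(n_mc_runs = 30, rng_seed = 7)
  sel <- cars_select(co$spectra, co$labels, cfg)
  expect_equal(sel$subset_size_by_run[1], 120L)          # run 1 = full grid
  expect_true(all(diff(sel$subset_size_by_run) <= 0))    # nonincreasing
  expect_equal(tail(sel$subset_size_by_run, 1), 2L)      # final run keeps 2
  expect_equal(sel$best_run, which.min(sel$rmsecv_by_run))
  expect_identical(sel$selected_indices, sel$subsets_by_run[[sel$best_run]])
  # selected subset beats (or ties) the full grid under the same partition
  expect_lte(sel$rmsecv_by_run[sel$best_run], sel$rmsecv_by_run[1])
  expect_equal(sel$selected_wavelengths_nm,
               co$spectra$wavelengths_nm[sel$selected_indices])

  expect_identical(sel$selected_indices,
                   cars_select(co$spectra, co$labels, cfg)$selected_indices)
  other <- cars_select(co$spectra, co$labels,
                       cars_config(n_mc_runs = 30, rng_seed = 8))
  expect_false(identical(sel$rmsecv_by_run, other$rmsecv_by_run))
})

test_that("CARS input validation catches degenerate cohorts", {
  co <- small_cohort(n = 4, n_points = 30)
  expect_error(cars_select(co$spectra, co$labels, cars_config(cv_folds = 5)),
               "samples per class")
  flat <- spectrum_set(1:10, matrix(rep(1:10, 30), 10),
                       sample_ids = sprintf("S%02d", 1:30))
  lab <- label_table(flat$sample_ids, rep(c("class1", "class2"), 15))
  expect_error(cars_select(flat, lab, cars_config()), "identical")
})

test_that("restriction keeps selected wavelengths in original order", {
  co <- small_cohort(n = 3, n_points = 501)
  idx <- sort(sample(501, 84))
  rs <- restrict_spectra(co$spectra, idx)
  expect_equal(n_wavelengths(rs), 84L)
  expect_equal(rs$wavelengths_nm, co$spectra$wavelengths_nm[idx])
  expect_equal(rs$values, co$spectra$values[idx, ])
  expect_equal(restrict_spectra(co$spectra, seq_len(501))$values,
               co$spectra$values)
  expect_error(restrict_spectra(co$spectra, integer(0)), "empty")
  expect_error(restrict_spectra(co$spectra, c(1, 502)), "outside")
})
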