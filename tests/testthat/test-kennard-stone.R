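test_that("equidistant samples split 3:1 with the seed pair first in order", {
  # regular tetrahedron: every pairwise distance equal (brute-force check)
  V <- t(matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1), 3))
  D <- as.matrix(dist(V))
  offd <- D[upper.tri(D)]
  expect_true(all(abs(offd - offd[1]) < 1e-12))

  ss <- spectrum_set(1:3, t(V) + 5, sample_ids = paste0("S", 1:4))
  sp <- kennard_stone_split(ss, per_class = FALSE, ratio = 3)
  expect_length(sp$calibration_ids, 3)
  expect_length(sp$prediction_ids, 1)
  # the maximal-distance seed pair (first in sample order on ties) is kept
  expect_true(all(c("S1", "S2") %in% sp$calibration_ids))
})

test_that("per-class quotas follow floor(3n/4) and the split is deterministic", {
  co <- generate_cohort(synthetic_config(n_per_class = c(11, 9),
                                         n_points = 40, rng_seed = 2))
  sp <- kennard_stone_split(co$spectra, co$labels)
  cal_lab <- truth_for(co$labels, sp$calibration_ids)
  expect_equal(sum(cal_lab == "class1"), floor(3 * 11 / 4))
  expect_equal(sum(cal_lab == "class2"), floor(3 * 9 / 4))
  expect_setequal(c(sp$calibration_ids, sp$prediction_ids),
                  co$spectra$sample_ids)
  expect_identical(sp, kennard_stone_split(co$spectra, co$labels))
})

test_that("the two most mutually distant samples of a class are calibrated", {
  co <- generate_cohort(synthetic_config(n_per_class = c(12, 12),
                                         n_points = 30, rng_seed = 5))
  sp <- kennard_stone_split(co$spectra, co$labels)
  for (cl in c("class1", "class2")) {
    ids <- co$labels$sample_id[co$labels$label == cl]
    D <- as.matrix(dist(t(co$spectra$values[, ids])))
    far <- which(D == max(D), arr.ind = TRUE)[1, ]
    expect_true(all(ids[far] %in% sp$calibration_ids))
  }
})

test_that("degenerate inputs are rejected", {
  co <- small_cohort(n = 4, n_points = 10)
  expect_error(kennard_stone_split(co$spectra, NULL, per_class = TRUE),
               "labels required")
})
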