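test_that("the image network has the published shape at full size", {
  net <- build_single_input_cnn(cnn_config(image_size = 300L), seed = 1)
  expect_equal(cnn_spatial_dims(net), c(150L, 75L, 37L))
  tab <- architecture_table(net)
  expect_equal(tab$out_channels[tab$layer == "Conv7"], 32L)
  expect_equal(tab$out_channels[grepl("^Conv", tab$layer)],
               c(8L, 8L, 16L, 16L, 32L, 32L, 32L))
  # standalone single-input head: fc1 and fc2 both have 2 nodes
  expect_equal(tab$out_channels[tab$layer %in% c("fc1", "fc2")], c(2L, 2L))
  expect_error(cnn_config(image_size = 4L), "too small")
})

test_that("SE weights are sigmoid-bounded channel attention", {
  net <- build_single_input_cnn(cnn_config(image_size = 32L), seed = 3)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  w <- extract_features(net, img, "se_weights")
  expect_length(w, 32L)
  expect_true(all(w > 0 & w < 1))
  # reduction factor 4: bottleneck is 8 wide
  expect_equal(dim(net$params$branch$se.W1), c(8L, 32L))
})

test_that("dual network predictions are softmax rows and order-sensitive", {
  cfg <- tiny_cnn_config()
  net <- build_dual_input_cnn(cfg, seed = 5)
  a <- array(runif(16 * 16 * 3), c(16, 16, 3))
  b <- array(runif(16 * 16 * 3), c(16, 16, 3))
  p_ab <- predict(net, list(gasf = list(s1 = a), gadf = list(s1 = b)))
  p_ba <- predict(net, list(gasf = list(s1 = b), gadf = list(s1 = a)))
  expect_equal(rowSums(p_ab$prob), 1, ignore_attr = TRUE)
  expect_true(all(p_ab$prob >= 0 & p_ab$prob <= 1))
  # branches are not weight-tied, so swapping the inputs changes the output
  expect_false(isTRUE(all.equal(p_ab$prob, p_ba$prob)))
  # full-size dual config uses 100-node branch fc layers
  tab <- architecture_table(build_dual_input_cnn(cnn_config(image_size = 16L),
                                                 seed = 1))
  expect_equal(tab$out_channels[tab$layer %in% c("fc1", "fc2", "fc3")],
               c(100L, 100L, 100L))
})

test_that("batch prediction equals concatenated per-sample prediction", {
  net <- build_single_input_cnn(tiny_cnn_config(), seed = 2)
  imgs <- lapply(1:4, function(i) array(runif(16 * 16 * 3), c(16, 16, 3)))
  names(imgs) <- paste0("s", 1:4)
  batch <- predict(net, imgs)$prob
  single <- do.call(rbind, lapply(imgs, function(x) predict(net, x)$prob))
  expect_equal(unname(batch), unname(single))
  expect_error(predict(net, array(0, c(8, 8, 3))), "shape")
})

test_that("training reduces the loss and is seed-reproducible", {
  co <- small_cohort(n = 8, n_points = 32, seed = 6)
  net <- build_cnn1d(32L, conv_channels = c(4L, 8L), fc_nodes = 16L, seed = 1)
  tc <- train_config(epochs = 8L, rng_seed = 2)
  m1 <- train_cnn(net, co$spectra, co$labels, tc)
  expect_length(m1$loss_history, 8L)
  expect_lt(tail(m1$loss_history, 1), m1$loss_history[1])
  m2 <- train_cnn(net, co$spectra, co$labels, tc)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$params, m2$params)

  one_class <- label_table(co$labels$sample_id,
                           rep("class1", nrow(co$labels)))
  expect_error(train_cnn(net, co$spectra, one_class, tc), "single class")
})

test_that("all baselines separate a well-separated cohort", {
  co <- generate_cohort(synthetic_config(n_per_class = c(20, 20),
                                         n_points = 64, rng_seed = 8))
  for (kind in c("plsda", "svm")) {
    m <- fit_baseline(kind, co$spectra, co$labels, seed = 1)
    expect_gte(prediction_accuracy(m, co$spectra, co$labels), 0.95)
  }
  m3 <- fit_baseline("cnn1d", co$spectra, co$labels, seed = 1,
                     tc = train_config(epochs = 30L, rng_seed = 1))
  expect_gte(prediction_accuracy(m3, co$spectra, co$labels), 0.95)
})

test_that("SVM predictions are invariant to duplicating a non-support vector", {
  co <- generate_cohort(synthetic_config(n_per_class = c(10, 10),
                                         n_points = 32, rng_seed = 9))
  m1 <- fit_baseline("svm", co$spectra, co$labels, seed = 1,
                     cost = 10, gamma = 1 / 32)
  # duplicating a sample with zero dual weight leaves the decision unchanged
  non_sv <- setdiff(seq_len(20), m1$fit$index)[1]
  expect_false(is.na(non_sv))
  dup_vals <- cbind(co$spectra$values, dup = co$spectra$values[, non_sv])
  dup <- spectrum_set(co$spectra$wavelengths_nm, dup_vals,
                      sample_ids = c(co$spectra$sample_ids, "dup"))
  dup_lab <- label_table(dup$sample_ids,
                         c(as.character(co$labels$label),
                           as.character(co$labels$label[non_sv])))
  m2 <- fit_baseline("svm", dup, dup_lab, seed = 1,
                     cost = 10, gamma = 1 / 32)
  expect_identical(as.character(predict(m1, co$spectra)$label),
                   as.character(predict(m2, co$spectra)$label))
})

test_that("shuffled labels give chance-level prediction accuracy", {
  accs <- vapply(1:2, function(s) {
    co <- generate_cohort(synthetic_config(n_per_class = c(40, 40),
                                           n_points = 64, rng_seed = s))
    shuffled <- label_table(co$labels$sample_id,
                            with_seed_local(s, sample(as.character(co$labels$label))))
    sp <- kennard_stone_split(co$spectra, shuffled)
    cal <- subset_samples(co$spectra, sp$calibration_ids)
    pred <- subset_samples(co$spectra, sp$prediction_ids)
    m <- fit_baseline("cnn1d", cal, shuffled, seed = s,
                      tc = train_config(epochs = 10L, rng_seed = s))
    prediction_accuracy(m, pred, shuffled)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("feature extraction exposes conv maps, SE weights and fc vectors", {
  cfg <- cnn_config(image_size = 32L)
  net <- build_dual_input_cnn(cfg, seed = 4)
  input <- list(gasf = array(runif(32 * 32 * 3), c(32, 32, 3)),
                gadf = array(runif(32 * 32 * 3), c(32, 32, 3)))
  f1 <- extract_features(net, input, "conv1")
  expect_s3_class(f1, "feature_map_set")
  expect_equal(dim(f1$maps)[3], 8L)
  f7 <- extract_features(net, input, "conv7", branch = "gadf")
  expect_equal(dim(f7$maps)[3], 32L)
  expect_length(f7$se_weights, 32L)
  expect_length(extract_features(net, input, "fc3"), 100L)
  expect_error(extract_features(net, input, "conv99"), "valid layers")
})
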