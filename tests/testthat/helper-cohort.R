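# shared fixtures, all generated in code

# small default-structure cohort on a reduced grid (fast)
small_cohort <- function(n = 15, n_points = 64, seed = 1) {
  generate_cohort(synthetic_config(n_per_class = c(n, n),
                                   n_points = n_points, rng_seed = seed))
}

# signal-free cohort: equal brightness and shape between classes
null_cohort <- function(n = 50, n_points = 501, seed = 1) {
  generate_cohort(synthetic_config(n_per_class = c(n, n),
                                   n_points = n_points,
                                   class_intensity_ratio = 1,
                                   peak_height_ratio = c(0.9, 0.9),
                                   rng_seed = seed))
}

# tiny network configuration for fast training tests
tiny_cnn_config <- function(image_size = 16L)
  cnn_config(image_size = image_size,
             conv_channels = list(c(4L, 4L), c(8L, 8L), c(8L, 8L, 8L)),
             se_reduction = 4L, branch_fc_nodes = c(20L, 20L),
             head_fc_nodes = 20L)

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

truth_for <- function(labels, ids)
  stats::setNames(as.character(labels$label[match(ids, labels$sample_id)]), ids)

prediction_accuracy <- function(model, inputs, labels) {
  pr <- predict(model, inputs)
  mean(as.character(pr$label) == truth_for(labels, names(pr$label)))
}
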