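#' CNN architecture configuration
#'
#' Describes the VGG-style stack used for GASF/GADF image classification:
#' seven 3x3 stride-1 convolutions in three stages (8, 8 | 16, 16 |
#' 32, 32, 32 channels), each stage followed by 2x2 stride-2 max pooling,
#' ReLU after every convolution, a Squeeze-and-Excitation block after the
#' last convolution, then fully connected layers. In a standalone
#' single-input network fc1 and fc2 have 2 nodes; as a fusion branch fc1 and
#' fc2 have 100 nodes and the two branch outputs are concatenated into a
#' head of fc3 (100, ReLU, dropout 0.1) and fc4 (2, softmax).
#'
#' @param image_size Input image side length in pixels (default 300).
#' @param conv_channels List of per-stage convolution channel vectors.
#' @param se_reduction SE bottleneck reduction factor (channels / reduction).
#' @param branch_fc_nodes fc1/fc2 sizes used when the network is a fusion
#'   branch.
#' @param standalone_fc_nodes fc1/fc2 sizes used when the single-input
#'   network classifies on its own.
#' @param head_fc_nodes fc3 size of the fusion head.
#' @param dropout Dropout rate applied after fc3.
#' @param n_classes Number of output classes (softmax width).
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(image_size = 300L,
                       conv_channels = list(c(8L, 8L), c(16L, 16L),
                                            c(32L, 32L, 32L)),
                       se_reduction = 4L,
                       branch_fc_nodes = c(100L, 100L),
                       standalone_fc_nodes = c(2L, 2L),
                       head_fc_nodes = 100L,
                       dropout = 0.1,
                       n_classes = 2L) {
  if (image_size < 2L^length(conv_channels))
    stop("image size too small for ", length(conv_channels), " pooling stages")
  structure(list(image_size = as.integer(image_size),
                 conv_channels = conv_channels,
                 se_reduction = as.integer(se_reduction),
                 branch_fc_nodes = branch_fc_nodes,
                 standalone_fc_nodes = standalone_fc_nodes,
                 head_fc_nodes = head_fc_nodes,
                 dropout = dropout, n_classes = as.integer(n_classes)),
            class = "cnn_config")
}

#' Training hyper-parameters
#'
#' Defaults follow the reference training protocol: batch size 10, 100
#' epochs, Adam with learning rate 0.001, cross-entropy loss.
#'
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param learning_rate Adam learning rate.
#' @param rng_seed Seed controlling shuffling and dropout; training is
#'   reproducible for a fixed seed within one runtime configuration.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 10L, epochs = 100L,
                         learning_rate = 0.001, rng_seed = 1L) {
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

branch_cfg_2d <- function(config, mode) {
  list(input_dim = c(config$image_size, config$image_size),
       in_channels = 3L,
       conv_channels = config$conv_channels,
       kernel = c(3L, 3L), pool = c(2L, 2L),
       use_se = TRUE, se_reduction = config$se_reduction,
       fc_nodes = if (mode == "standalone")
         c(config$standalone_fc_nodes[1], config$n_classes)
       else config$branch_fc_nodes,
       fc_final_linear = mode == "standalone")
}

#' Build the single-input GAF network (untrained)
#'
#' @param config A [cnn_config()].
#' @param source Which Gramian image the network consumes (metadata).
#' @param seed Seed for the Kaiming-uniform weight initialisation.
#' @return An object of class `gafnet`, kind `cnn2d_single`.
#' @export
build_single_input_cnn <- function(config = cnn_config(),
                                   source = c("gasf", "gadf"), seed = 1L) {
  source <- match.arg(source)
  bcfg <- branch_cfg_2d(config, "standalone")
  branch_spatial_dims(bcfg)  # validates the size
  params <- with_seed(seed, list(branch = branch_init(bcfg)))
  new_gafnet("cnn2d_single", config, params, branch_cfg = bcfg,
             preprocessing = list(source = source))
}

#' Build the dual-input (GASF + GADF) fusion network (untrained)
#'
#' Two independent (not weight-tied) single-input branches process the GASF
#' and GADF images; their fc2 feature vectors are concatenated and passed
#' through fc3 (ReLU, dropout) and fc4 (softmax).
#'
#' @param config A [cnn_config()].
#' @param seed Seed for weight initialisation.
#' @return An object of class `gafnet`, kind `cnn2d_dual`.
#' @export
build_dual_input_cnn <- function(config = cnn_config(), seed = 1L) {
  bcfg <- branch_cfg_2d(config, "branch")
  branch_spatial_dims(bcfg)
  nfeat <- 2L * utils::tail(bcfg$fc_nodes, 1)
  params <- with_seed(seed, list(
    gasf = branch_init(bcfg),
    gadf = branch_init(bcfg),
    head = list(fc3.W = init_mat(config$head_fc_nodes, nfeat),
                fc3.b = numeric(config$head_fc_nodes),
                fc4.W = init_mat(config$n_classes, config$head_fc_nodes),
                fc4.b = numeric(config$n_classes))))
  new_gafnet("cnn2d_dual", config, params, branch_cfg = bcfg,
             preprocessing = list(source = c("gasf", "gadf")))
}

#' Build the 1-D spectral CNN (untrained)
#'
#' A 1-D convolutional stack mirroring the image network's design idiom
#' ("Tian-style"): three conv-pool blocks of 8, 16 and 32 channels with
#' kernel 3 and ReLU, then fc layers 100 -> 2 with softmax. Spectra are
#' standardised per wavelength with calibration statistics learned in
#' [train_cnn()].
#'
#' @param input_length Number of wavelengths.
#' @param conv_channels Integer vector, channels of each conv-pool block.
#' @param fc_nodes Hidden fc sizes before the softmax layer.
#' @param n_classes Softmax width.
#' @param seed Seed for weight initialisation.
#' @return An object of class `gafnet`, kind `cnn1d`.
#' @export
build_cnn1d <- function(input_length, conv_channels = c(8L, 16L, 32L),
                        fc_nodes = 100L, n_classes = 2L, seed = 1L) {
  bcfg <- list(input_dim = c(as.integer(input_length), 1L), in_channels = 1L,
               conv_channels = as.list(conv_channels),
               kernel = c(3L, 1L), pool = c(2L, 1L),
               use_se = FALSE,
               fc_nodes = c(fc_nodes, n_classes), fc_final_linear = TRUE)
  branch_spatial_dims(bcfg)
  params <- with_seed(seed, list(branch = branch_init(bcfg)))
  cfg <- structure(list(input_length = as.integer(input_length),
                        conv_channels = conv_channels, fc_nodes = fc_nodes,
                        n_classes = as.integer(n_classes), dropout = 0),
                   class = "cnn_config")
  new_gafnet("cnn1d", cfg, params, branch_cfg = bcfg, preprocessing = list())
}

new_gafnet <- function(kind, config, params, branch_cfg, preprocessing) {
  structure(list(kind = kind, config = config, params = params,
                 branch_cfg = branch_cfg, preprocessing = preprocessing,
                 class_order = c("class1", "class2"),
                 trained = FALSE, loss_history = numeric(0)),
            class = "gafnet")
}

#' @export
print.gafnet <- function(x, ...) {
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf("<gafnet> kind = %s, %s, %d parameters\n", x$kind,
              if (x$trained) sprintf("trained (%d epochs)",
                                     length(x$loss_history)) else "untrained",
              np))
  invisible(x)
}

#' @export
summary.gafnet <- function(object, ...) {
  print(object)
  print(architecture_table(object))
  if (object$trained)
    cat(sprintf("final training loss: %.4f\n",
                utils::tail(object$loss_history, 1)))
  invisible(object)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# ---- forward passes -------------------------------------------------------

# input: single -> H x W x 3 array; dual -> list(gasf=, gadf=); cnn1d ->
# numeric vector (raw; standardised here if stats are available)
gafnet_forward <- function(model, input, train = FALSE) {
  if (model$kind == "cnn2d_dual") {
    fa <- branch_forward(model$params$gasf, model$branch_cfg, input$gasf)
    fb <- branch_forward(model$params$gadf, model$branch_cfg, input$gadf)
    feat <- c(fa$out, fb$out)
    h <- model$params$head
    z3 <- as.numeric(h$fc3.W %*% feat + h$fc3.b)
    a3 <- relu(z3)
    mask <- if (train && model$config$dropout > 0)
      (stats::runif(length(a3)) >= model$config$dropout) /
        (1 - model$config$dropout)
    else rep(1, length(a3))
    d3 <- a3 * mask
    z4 <- as.numeric(h$fc4.W %*% d3 + h$fc4.b)
    probs <- as.numeric(softmax_rows(matrix(z4, 1)))
    list(probs = probs,
         cache = list(a = fa$cache, b = fb$cache, feat = feat, z3 = z3,
                      a3 = a3, mask = mask, d3 = d3),
         features = list(gasf = fa$features, gadf = fb$features,
                         fc3 = a3))
  } else {
    x <- if (model$kind == "cnn1d") cnn1d_input(model, input) else input
    fa <- branch_forward(model$params$branch, model$branch_cfg, x)
    probs <- as.numeric(softmax_rows(matrix(fa$out, 1)))
    list(probs = probs, cache = fa$cache, features = fa$features)
  }
}

gafnet_backward <- function(model, cache, dlogits) {
  if (model$kind == "cnn2d_dual") {
    h <- model$params$head
    grads <- list(head = list())
    grads$head$fc4.W <- outer(dlogits, cache$d3)
    grads$head$fc4.b <- dlogits
    dd3 <- as.numeric(crossprod(h$fc4.W, dlogits))
    dz3 <- dd3 * cache$mask * (cache$z3 > 0)
    grads$head$fc3.W <- outer(dz3, cache$feat)
    grads$head$fc3.b <- dz3
    dfeat <- as.numeric(crossprod(h$fc3.W, dz3))
    nb <- length(cache$feat) / 2L
    grads$gasf <- branch_backward(model$params$gasf, model$branch_cfg,
                                  cache$a, dfeat[seq_len(nb)])
    grads$gadf <- branch_backward(model$params$gadf, model$branch_cfg,
                                  cache$b, dfeat[nb + seq_len(nb)])
    grads
  } else {
    list(branch = branch_backward(model$params$branch, model$branch_cfg,
                                  cache, dlogits))
  }
}

cnn1d_input <- function(model, values) {
  v <- as.numeric(values)
  if (length(v) != model$branch_cfg$input_dim[1])
    stop("spectrum length does not match the trained input length")
  st <- model$preprocessing$standardize
  if (!is.null(st)) v <- (v - st$mean) / st$sd
  array(v, dim = c(length(v), 1L, 1L))
}

# ---- training -------------------------------------------------------------

#' Train a GAF network with Adam
#'
#' Minimises softmax cross-entropy with mini-batch Adam. The per-epoch mean
#' training loss is recorded in `loss_history`.
#'
#' @param model An untrained (or previously trained) [build_single_input_cnn()],
#'   [build_dual_input_cnn()] or [build_cnn1d()] network.
#' @param images Training inputs, named by sample id. For a single-input
#'   network: a list of `H x W x 3` arrays in `[0, 1]`. For the dual network:
#'   `list(gasf = <list of arrays>, gadf = <list of arrays>)`. For the 1-D
#'   network: a [spectrum_set()] (per-wavelength standardisation statistics
#'   are learned here and stored in the model's preprocessing recipe).
#' @param labels A [label_table()] covering every training sample.
#' @param tc A [train_config()].
#' @return The trained `gafnet`.
#' @export
train_cnn <- function(model, images, labels, tc = train_config()) {
  stopifnot(inherits(model, "gafnet"), inherits(tc, "train_config"))
  if (model$kind == "cnn1d") {
    stopifnot(inherits(images, "spectrum_set"))
    mu <- rowMeans(images$values)
    sd <- apply(images$values, 1, stats::sd)
    if (all(sd == 0)) stop("degenerate spectra: constant at every wavelength")
    sd[sd == 0] <- 1
    model$preprocessing$standardize <- list(mean = mu, sd = sd)
    ids <- images$sample_ids
    get_input <- function(id) images$values[, id]
  } else if (model$kind == "cnn2d_dual") {
    ids <- names(images$gasf)
    if (!identical(ids, names(images$gadf)))
      stop("gasf and gadf image lists must cover the same samples")
    get_input <- function(id) list(gasf = images$gasf[[id]],
                                   gadf = images$gadf[[id]])
  } else {
    ids <- names(images)
    get_input <- function(id) images[[id]]
  }
  y <- labels_for_ids(ids, labels)
  if (length(unique(y)) < 2L)
    stop("training set contains a single class")
  onehot <- cbind(y == "class1", y == "class2") * 1

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(tc$rng_seed)

  state <- adam_init(flatten_params(model$params))
  n <- length(ids)
  loss_hist <- numeric(tc$epochs)
  for (epoch in seq_len(tc$epochs)) {
    ord <- sample(n)
    total_loss <- 0
    for (start in seq(1, n, by = tc$batch_size)) {
      batch <- ord[start:min(start + tc$batch_size - 1, n)]
      gsum <- NULL
      for (i in batch) {
        fw <- gafnet_forward(model, get_input(ids[i]), train = TRUE)
        total_loss <- total_loss - log(max(fw$probs[onehot[i, ] == 1], 1e-12))
        dlogits <- fw$probs - onehot[i, ]
        g <- flatten_params(gafnet_backward(model, fw$cache, dlogits))
        gsum <- acc_grads(gsum, g)
      }
      gmean <- scale_grads(gsum, 1 / length(batch))
      flat <- flatten_params(model$params)
      upd <- adam_step(flat, gmean, state, lr = tc$learning_rate)
      state <- upd$state
      model$params <- unflatten_params(upd$params, model$params)
    }
    loss_hist[epoch] <- total_loss / n
  }
  model$trained <- TRUE
  model$loss_history <- c(model$loss_history, loss_hist)
  model$train_config <- tc
  model
}

labels_for_ids <- function(ids, labels) {
  i <- match(ids, labels$sample_id)
  if (anyNA(i)) stop("labels missing for samples: ",
                     paste(ids[is.na(i)], collapse = ", "))
  as.character(labels$label[i])
}

# nested branch/head param lists <-> one flat named list for Adam
flatten_params <- function(p) {
  out <- list()
  for (nm in names(p)) {
    if (is.list(p[[nm]])) {
      sub <- p[[nm]]
      names(sub) <- paste0(nm, "/", names(sub))
      out <- c(out, sub)
    } else out[[nm]] <- p[[nm]]
  }
  out
}

unflatten_params <- function(flat, template) {
  for (nm in names(template)) {
    if (is.list(template[[nm]])) {
      for (sub in names(template[[nm]]))
        template[[nm]][[sub]] <- flat[[paste0(nm, "/", sub)]]
    } else template[[nm]] <- flat[[nm]]
  }
  template
}

# ---- prediction -----------------------------------------------------------

#' Predict class probabilities and labels from a GAF network
#'
#' @param object A trained `gafnet`.
#' @param newdata Inputs in the same format as [train_cnn()]'s `images`.
#' @param ... Unused.
#' @return A list with `prob` (matrix, one row per sample, columns `class1`,
#'   `class2`, rows summing to 1) and `label` (factor; ties resolve to
#'   `class1`).
#' @export
predict.gafnet <- function(object, newdata, ...) {
  inputs <- prediction_inputs(object, newdata)
  prob <- t(vapply(inputs,
                   function(x) gafnet_forward(object, x, train = FALSE)$probs,
                   numeric(object$config$n_classes)))
  colnames(prob) <- object$class_order
  lab <- factor(object$class_order[max.col(prob, ties.method = "first")],
                levels = object$class_order)
  names(lab) <- rownames(prob)
  list(prob = prob, label = lab)
}

prediction_inputs <- function(model, newdata) {
  if (model$kind == "cnn1d") {
    stopifnot(inherits(newdata, "spectrum_set"))
    st <- model$preprocessing$standardize
    if (!is.null(st) && length(st$mean) != nrow(newdata$values))
      stop("wavelength grid does not match the model's preprocessing recipe")
    out <- lapply(newdata$sample_ids, function(id) newdata$values[, id])
    names(out) <- newdata$sample_ids
  } else if (model$kind == "cnn2d_dual") {
    check_image_dim(model, newdata$gasf[[1]])
    out <- lapply(names(newdata$gasf), function(id)
      list(gasf = newdata$gasf[[id]], gadf = newdata$gadf[[id]]))
    names(out) <- names(newdata$gasf)
  } else {
    if (is.array(newdata) && length(dim(newdata)) == 3) newdata <- list(newdata)
    check_image_dim(model, newdata[[1]])
    out <- newdata
  }
  out
}

check_image_dim <- function(model, img) {
  want <- c(model$config$image_size, model$config$image_size, 3L)
  if (!identical(as.integer(dim(img)), as.integer(want)))
    stop(sprintf("input image shape (%s) does not match the model (%s)",
                 paste(dim(img), collapse = "x"),
                 paste(want, collapse = "x")))
}

# ---- inspection -----------------------------------------------------------

#' Extract intermediate features from a trained network
#'
#' @param model A `gafnet`.
#' @param input One input in the network's format (a single image array, a
#'   `list(gasf=, gadf=)` pair, or a numeric spectrum for `cnn1d`).
#' @param layer One of the network's layer names: `conv1` ... `conv7`
#'   (feature maps), `se_weights` (SE channel weights), or `fc1`/`fc2`
#'   (`fc3` on the dual network) for activation vectors.
#' @param branch For the dual network, which branch to read conv/fc/SE
#'   features from.
#' @return For conv layers, a `feature_map_set`: list with `layer_name`,
#'   `maps` (H x W x S array) and, for the post-SE stage, `se_weights`.
#'   For fc layers and `se_weights`, a numeric vector.
#' @export
extract_features <- function(model, input, layer, branch = c("gasf", "gadf")) {
  stopifnot(inherits(model, "gafnet"))
  branch <- match.arg(branch)
  fw <- gafnet_forward(model, input, train = FALSE)
  feats <- if (model$kind == "cnn2d_dual") {
    c(fw$features[[branch]], list(fc3 = fw$features$fc3))
  } else fw$features
  valid <- names(feats)[names(feats) != "se_out"]
  if (!layer %in% valid)
    stop("unknown layer '", layer, "'; valid layers: ",
         paste(valid, collapse = ", "))
  val <- feats[[layer]]
  if (grepl("^conv", layer)) {
    structure(list(layer_name = layer, maps = val,
                   se_weights = if (identical(layer, last_conv_name(model)))
                     feats$se_weights),
              class = "feature_map_set")
  } else val
}

last_conv_name <- function(model)
  paste0("conv", sum(lengths(model$branch_cfg$conv_channels)))

#' Architecture table of a built network
#'
#' Programmatic walk over the instantiated parameters, reporting one row per
#' layer (kernel, stride, output channels/nodes, activation) in the order the
#' data flows. Useful to verify that a built network matches its published
#' layer table.
#'
#' @param model A `gafnet`.
#' @return A data frame with columns `layer`, `kernel_size`, `stride`,
#'   `out_channels`, `activation`, `value`.
#' @export
architecture_table <- function(model) {
  stopifnot(inherits(model, "gafnet"))
  cfg <- model$branch_cfg
  pb <- if (model$kind == "cnn2d_dual") model$params$gasf else model$params$branch
  kh <- cfg$kernel[1]; kw <- cfg$kernel[2]
  row <- function(layer, kernel = "", stride = NA, ch = NA, act = "",
                  value = "")
    data.frame(layer = layer, kernel_size = kernel, stride = stride,
               out_channels = ch, activation = act, value = value,
               stringsAsFactors = FALSE)
  rows <- row("Image",
              value = paste(c(cfg$input_dim[1],
                              if (cfg$input_dim[2] > 1) cfg$input_dim[2],
                              cfg$in_channels), collapse = " x "))
  i <- 0L
  for (s in seq_along(cfg$conv_channels)) {
    for (ch in cfg$conv_channels[[s]]) {
      i <- i + 1L
      rows <- rbind(rows, row(paste0("Conv", i),
                              kernel = paste(kh, "x", kw), stride = 1L,
                              ch = nrow(pb[[paste0("conv", i, ".W")]]),
                              act = "ReLU"))
    }
    rows <- rbind(rows, row(paste0("MaxPool", s),
                            kernel = paste(cfg$pool[1], "x", cfg$pool[2]),
                            stride = cfg$pool[1]))
  }
  if (isTRUE(cfg$use_se))
    rows <- rbind(rows, row("SE", ch = length(pb$se.b2), act = "Sigmoid"))
  nfc <- length(cfg$fc_nodes)
  for (j in seq_len(nfc))
    rows <- rbind(rows, row(paste0("fc", j),
                            ch = nrow(pb[[paste0("fc", j, ".W")]]),
                            act = if (j == nfc && isTRUE(cfg$fc_final_linear))
                              "Softmax" else "ReLU"))
  if (model$kind == "cnn2d_dual") {
    h <- model$params$head
    rows <- rbind(rows,
                  row("fc3", ch = nrow(h$fc3.W), act = "ReLU"),
                  row("drop", value = format(model$config$dropout)),
                  row("fc4", ch = nrow(h$fc4.W), act = "Softmax"))
  }
  rows
}

#' Spatial dimensions after each pooling stage
#'
#' @param model A `gafnet`.
#' @return Integer vector of post-pooling heights (for 2-D networks the maps
#'   are square, so width equals height).
#' @export
cnn_spatial_dims <- function(model) {
  vapply(branch_spatial_dims(model$branch_cfg), `[`, integer(1), 1L)
}
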