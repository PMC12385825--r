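#' Pipeline run configuration
#'
#' Bundles every stage's parameters for an end-to-end run: cohort input
#' (CSV paths or the synthetic generator), optional CARS selection, the
#' Kennard-Stone split, GAF encoding, one model, and evaluation. Every
#' effective parameter is captured in the run manifest so a run can be
#' replayed.
#'
#' @param output_dir Directory to create the run artifacts in.
#' @param spectra_csv,labels_csv Input CSVs ([read_spectra()] layout); when
#'   `NULL` the synthetic generator supplies the cohort.
#' @param synth A [synthetic_config()] (used when no CSVs are given).
#' @param use_cars Run CARS wavelength selection before encoding.
#' @param cars A [cars_config()].
#' @param split_ratio Kennard-Stone calibration:prediction ratio.
#' @param model Which classifier to train: `"gaf"` (dual input), `"gasf"`,
#'   `"gadf"` (single input), `"cnn1d"`, `"plsda"`, `"svm"`.
#' @param image_size GAF image side length for the CNN models.
#' @param colormap Colormap for image rendering.
#' @param cnn A [cnn_config()] (its `image_size` is overridden by
#'   `image_size`).
#' @param train A [train_config()].
#' @param seed Global seed; stage seeds are derived from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(output_dir,
                       spectra_csv = NULL, labels_csv = NULL,
                       synth = synthetic_config(),
                       use_cars = FALSE, cars = cars_config(),
                       split_ratio = 3,
                       model = c("gaf", "gasf", "gadf", "cnn1d", "plsda", "svm"),
                       image_size = 96L, colormap = "viridis",
                       cnn = cnn_config(image_size = image_size),
                       train = train_config(epochs = 30L),
                       seed = 1L) {
  model <- match.arg(model)
  cnn$image_size <- as.integer(image_size)
  structure(list(output_dir = output_dir, spectra_csv = spectra_csv,
                 labels_csv = labels_csv, synth = synth,
                 use_cars = use_cars, cars = cars,
                 split_ratio = split_ratio, model = model,
                 image_size = as.integer(image_size), colormap = colormap,
                 cnn = cnn, train = train, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the classification pipeline end to end
#'
#' Stage order: load/generate spectra, optional CARS selection, GAF encoding
#' (for image models), Kennard-Stone split, model training, evaluation on
#' the calibration and prediction sets. All artifacts (CSV tables, selection
#' and split JSON, metrics JSON, example GAF PNGs, and a manifest with file
#' checksums) are written to `config$output_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `run_dir`, `model`, `selection`, `split`
#'   and `metrics` (per evaluated set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)

  if (is.null(config$spectra_csv)) {
    config$synth$rng_seed <- config$seed
    cohort <- generate_cohort(config$synth)
    spectra <- cohort$spectra; labels <- cohort$labels
  } else {
    if (is.null(config$labels_csv)) stop("stage 'load': labels_csv missing")
    spectra <- read_spectra(config$spectra_csv)
    labels <- read_labels(config$labels_csv)
  }
  write_spectra(spectra, out("spectra.csv"))
  write_labels(labels, out("labels.csv"))

  selection <- NULL
  model_spectra <- spectra
  if (isTRUE(config$use_cars)) {
    config$cars$rng_seed <- config$seed + 1L
    selection <- cars_select(spectra, labels, config$cars)
    write_selection(selection, out("selection.json"))
    model_spectra <- restrict_spectra(spectra, selection)
  }

  split <- kennard_stone_split(spectra, labels, ratio = config$split_ratio)
  jsonlite::write_json(split[c("calibration_ids", "prediction_ids")],
                       out("split.json"))

  cal <- subset_samples(model_spectra, split$calibration_ids)
  pred <- subset_samples(model_spectra, split$prediction_ids)
  config$train$rng_seed <- config$seed + 2L

  if (config$model %in% c("gaf", "gasf", "gadf")) {
    enc_cal <- encode_gaf_images(cal, config$image_size, config$colormap)
    enc_pred <- encode_gaf_images(pred, config$image_size, config$colormap)
    first <- cal$sample_ids[1]
    for (src in c("gasf", "gadf")) {
      pair <- gaf_pair(cal$values[, first])
      write_gaf_png(render_gaf_image(pair[[src]], config$image_size,
                                     config$colormap, source = src),
                    out(sprintf("example_%s.png", src)), sample_id = first,
                    wavelengths_nm = cal$wavelengths_nm)
    }
    if (config$model == "gaf") {
      net <- build_dual_input_cnn(config$cnn, seed = config$seed + 3L)
      model <- train_cnn(net, enc_cal, labels, config$train)
      eval_in <- list(calibration = enc_cal, prediction = enc_pred)
    } else {
      net <- build_single_input_cnn(config$cnn, source = config$model,
                                    seed = config$seed + 3L)
      model <- train_cnn(net, enc_cal[[config$model]], labels, config$train)
      eval_in <- list(calibration = enc_cal[[config$model]],
                      prediction = enc_pred[[config$model]])
    }
  } else if (config$model == "cnn1d") {
    net <- build_cnn1d(n_wavelengths(cal), seed = config$seed + 3L)
    model <- train_cnn(net, cal, labels, config$train)
    eval_in <- list(calibration = cal, prediction = pred)
  } else {
    model <- fit_baseline(config$model, cal, labels, seed = config$seed + 3L)
    eval_in <- list(calibration = cal, prediction = pred)
  }

  metrics_by_set <- list()
  for (set in names(eval_in)) {
    pr <- predict(model, eval_in[[set]])
    ids <- names(pr$label)
    truth <- stats::setNames(labels_for_ids(ids, labels), ids)
    rep <- metrics(confusion(truth, pr$label))
    write_metrics(rep, out(sprintf("metrics_%s.json", set)))
    metrics_by_set[[set]] <- rep
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gaffuse")),
    seed = config$seed, model = config$model,
    n_samples = n_samples(spectra),
    n_wavelengths_full = n_wavelengths(spectra),
    n_wavelengths_used = n_wavelengths(model_spectra),
    use_cars = isTRUE(config$use_cars),
    image_size = config$image_size, colormap = config$colormap,
    split_ratio = config$split_ratio,
    train = unclass(config$train),
    synthetic = if (is.null(config$spectra_csv)) unclass(config$synth),
    cars = if (isTRUE(config$use_cars)) unclass(config$cars))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  files <- setdiff(list.files(config$output_dir), "manifest_files.json")
  jsonlite::write_json(
    list(files = as.list(tools::md5sum(out(files)))),
    out("manifest_files.json"), auto_unbox = TRUE)

  invisible(list(run_dir = config$output_dir, model = model,
                 selection = selection, split = split,
                 metrics = metrics_by_set))
}
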