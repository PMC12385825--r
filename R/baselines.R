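#' Fit a baseline classifier on 1-D spectra
#'
#' The three reference models trained directly on transmittance intensity
#' spectra: PLS-DA (dummy-coded 0/1 response on the in-package SIMPLS kernel,
#' component count chosen by 5-fold cross-validation), an RBF-kernel SVM
#' (`e1071::svm`, cost/gamma chosen by cross-validated grid search), and the
#' 1-D CNN ([build_cnn1d()] trained with [train_cnn()]).
#'
#' @param kind One of `"plsda"`, `"svm"`, `"cnn1d"`.
#' @param spectra Calibration [spectrum_set()] in intensity mode.
#' @param labels A [label_table()].
#' @param seed Integer seed for any cross-validation or training randomness.
#' @param tc A [train_config()] (used by `cnn1d` only; default 100 epochs).
#' @param cost,gamma Optional fixed SVM hyper-parameters; when both are given
#'   the cross-validated grid search is skipped.
#' @return A classed model object with a [predict()] method returning
#'   `list(prob, label)`.
#' @export
fit_baseline <- function(kind = c("plsda", "svm", "cnn1d"), spectra, labels,
                         seed = 1L, tc = train_config(rng_seed = seed),
                         cost = NULL, gamma = NULL) {
  kind <- match.arg(kind)
  if (spectra$mode != "intensity")
    stop("baselines model transmittance intensity spectra")
  if (max(abs(apply(spectra$values, 1, stats::sd))) == 0)
    stop("degenerate spectra: every wavelength is constant")
  y <- labels_for(spectra, labels)
  if (length(unique(y)) < 2L) stop("calibration set contains a single class")
  switch(kind,
         plsda = fit_plsda(spectra, y, seed),
         svm = fit_svm(spectra, y, seed, cost = cost, gamma = gamma),
         cnn1d = {
           model <- with_seed(seed, build_cnn1d(n_wavelengths(spectra),
                                                seed = seed))
           train_cnn(model, spectra, labels, tc)
         })
}

fit_plsda <- function(spectra, y, seed, max_ncomp = 10L) {
  X <- t(spectra$values)
  yd <- as.numeric(y == "class2")
  ncomp_cap <- min(max_ncomp, ncol(X), nrow(X) - 2L)
  fold_id <- with_seed(seed, sample(rep_len(1:5, nrow(X))))
  cv <- pls_rmsecv(X, yd, fold_id, ncomp_cap)
  fit <- simpls_fit(X, yd, ncomp_cap)
  structure(list(fit = fit, ncomp = min(cv$ncomp, fit$ncomp),
                 wavelengths_nm = spectra$wavelengths_nm,
                 class_order = c("class1", "class2")),
            class = c("plsda_model", "baseline_model"))
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d wavelengths, %d latent components\n",
              length(x$wavelengths_nm), x$ncomp))
  invisible(x)
}

#' Predict from a PLS-DA baseline
#'
#' The latent-score prediction of the 0/1 dummy response is thresholded at
#' 0.5; the clipped score doubles as a pseudo-probability of class 2.
#'
#' @param object A `plsda_model` from [fit_baseline()].
#' @param newdata A [spectrum_set()] on the training grid, or a matrix with
#'   samples in rows.
#' @param ... Unused.
#' @return `list(prob, label, score)`.
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  X <- baseline_newdata(object, newdata)
  score <- predict(object$fit, X, ncomp = object$ncomp)
  p2 <- pmin(pmax(score, 0), 1)
  prob <- cbind(class1 = 1 - p2, class2 = p2)
  rownames(prob) <- rownames(X)
  lab <- factor(ifelse(score >= 0.5, "class2", "class1"),
                levels = object$class_order)
  names(lab) <- rownames(X)
  list(prob = prob, label = lab, score = score)
}

fit_svm <- function(spectra, y, seed, cost = NULL, gamma = NULL) {
  X <- t(spectra$values)
  yf <- factor(y, levels = c("class1", "class2"))
  if (!is.null(cost) && !is.null(gamma)) {
    fit <- e1071::svm(X, yf, kernel = "radial", cost = cost, gamma = gamma)
    return(structure(list(fit = fit, cost = cost, gamma = gamma,
                          cv_accuracy = NA_real_,
                          wavelengths_nm = spectra$wavelengths_nm,
                          class_order = c("class1", "class2")),
                     class = c("svm_model", "baseline_model")))
  }
  g0 <- 1 / ncol(X)
  grid <- expand.grid(cost = c(1, 10, 100), gamma = g0 * c(0.1, 1, 10))
  fold_id <- with_seed(seed, sample(rep_len(1:5, nrow(X))))
  acc <- apply(grid, 1, function(gp) {
    hits <- 0
    for (f in 1:5) {
      tr <- fold_id != f
      m <- e1071::svm(X[tr, , drop = FALSE], yf[tr], kernel = "radial",
                      cost = gp[["cost"]], gamma = gp[["gamma"]])
      hits <- hits + sum(predict(m, X[!tr, , drop = FALSE]) == yf[!tr])
    }
    hits / nrow(X)
  })
  best <- grid[which.max(acc), ]
  fit <- e1071::svm(X, yf, kernel = "radial", cost = best$cost,
                    gamma = best$gamma)
  structure(list(fit = fit, cost = best$cost, gamma = best$gamma,
                 cv_accuracy = max(acc),
                 wavelengths_nm = spectra$wavelengths_nm,
                 class_order = c("class1", "class2")),
            class = c("svm_model", "baseline_model"))
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("<svm_model> RBF, cost = %g, gamma = %g (CV accuracy %.3f)\n",
              x$cost, x$gamma, x$cv_accuracy))
  invisible(x)
}

#' Predict from the RBF-SVM baseline
#'
#' @param object An `svm_model` from [fit_baseline()].
#' @param newdata A [spectrum_set()] or sample-rows matrix.
#' @param ... Unused.
#' @return `list(prob, label)`; probabilities are a logistic transform of the
#'   signed decision value.
#' @export
predict.svm_model <- function(object, newdata, ...) {
  X <- baseline_newdata(object, newdata)
  pred <- predict(object$fit, X, decision.values = TRUE)
  dv <- attr(pred, "decision.values")[, 1]
  # decision value is signed toward the first factor level (class1)
  p1 <- sigmoid(dv)
  prob <- cbind(class1 = p1, class2 = 1 - p1)
  rownames(prob) <- rownames(X)
  lab <- factor(as.character(pred), levels = object$class_order)
  names(lab) <- rownames(X)
  list(prob = prob, label = lab)
}

baseline_newdata <- function(object, newdata) {
  if (inherits(newdata, "spectrum_set")) {
    if (length(newdata$wavelengths_nm) != length(object$wavelengths_nm))
      stop("wavelength grid does not match the fitted model")
    t(newdata$values)
  } else as.matrix(newdata)
}

#' Best single-wavelength threshold classifier
#'
#' The naive reference that classifies on one intensity value alone: for
#' every wavelength, the cut point between the two class means (searched over
#' all calibration midpoints, in either direction) that maximises calibration
#' accuracy is found, and the single best wavelength is kept. Serves as the
#' floor that multivariate models must beat.
#'
#' @param spectra A [spectrum_set()].
#' @param labels A [label_table()].
#' @param calibration_ids,prediction_ids Sample-id partition.
#' @return List with `wavelength_nm`, `index`, `threshold`, `direction`,
#'   `calibration_accuracy`, `prediction_accuracy`.
#' @export
single_wavelength_threshold <- function(spectra, labels, calibration_ids,
                                        prediction_ids) {
  y_cal <- labels_for_ids(calibration_ids, labels) == "class2"
  best <- list(acc = -1)
  for (i in seq_len(n_wavelengths(spectra))) {
    v <- spectra$values[i, calibration_ids]
    o <- order(v)
    vs <- v[o]; ys <- y_cal[o]
    cum2 <- cumsum(ys)                       # class2 among the k smallest
    n2 <- sum(y_cal); n <- length(y_cal)
    k <- seq_len(n - 1)
    acc_hi <- (k - cum2[k] + n2 - cum2[k]) / n           # class2 above the cut
    acc_lo <- (cum2[k] + (n - n2) - (k - cum2[k])) / n   # class2 below the cut
    j_hi <- which.max(acc_hi); j_lo <- which.max(acc_lo)
    cand <- if (acc_hi[j_hi] >= acc_lo[j_lo])
      list(acc = acc_hi[j_hi], dir = "high", j = j_hi)
    else list(acc = acc_lo[j_lo], dir = "low", j = j_lo)
    if (cand$acc > best$acc)
      best <- list(acc = cand$acc, index = i, dir = cand$dir,
                   thr = (vs[cand$j] + vs[cand$j + 1]) / 2)
  }
  classify <- function(ids) {
    v <- spectra$values[best$index, ids]
    hi <- v > best$thr
    pred <- if (best$dir == "high") ifelse(hi, "class2", "class1")
            else ifelse(hi, "class1", "class2")
    mean(pred == labels_for_ids(ids, labels))
  }
  list(wavelength_nm = spectra$wavelengths_nm[best$index], index = best$index,
       threshold = best$thr, direction = best$dir,
       calibration_accuracy = best$acc,
       prediction_accuracy = classify(prediction_ids))
}
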