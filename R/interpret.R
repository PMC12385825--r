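#' 2-D projection of spectra or learned features
#'
#' PCA returns the first two principal-component scores together with the
#' per-component explained-variance fractions; t-SNE returns a seeded 2-D
#' embedding computed by an exact (all-pairs) implementation suited to
#' cohort-sized data.
#'
#' @param x A [spectrum_set()] or a numeric matrix with samples in rows
#'   (e.g. fc3 feature vectors).
#' @param method `"pca"` or `"tsne"`.
#' @param seed Seed for the t-SNE initialisation.
#' @param perplexity t-SNE perplexity (clamped to `(n - 1) / 3`).
#' @param n_iter t-SNE gradient-descent iterations.
#' @return A data frame of class `embedding2d` with columns `sample_id`,
#'   `x`, `y`; attributes `method`, `params` and (for PCA)
#'   `explained_variance` (fractions for PC1 and PC2).
#' @export
project <- function(x, method = c("pca", "tsne"), seed = 1L,
                    perplexity = 30, n_iter = 500L) {
  method <- match.arg(method)
  X <- if (inherits(x, "spectrum_set")) t(x$values) else as.matrix(x)
  ids <- if (!is.null(rownames(X))) rownames(X) else as.character(seq_len(nrow(X)))
  if (nrow(X) < 3L) stop("need at least 3 samples to project")
  if (method == "pca") {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    ev <- pc$sdev^2 / sum(pc$sdev^2)
    out <- data.frame(sample_id = ids, x = pc$x[, 1], y = pc$x[, 2])
    attr(out, "explained_variance") <- ev[1:2]
    attr(out, "params") <- list(components = 1:2)
  } else {
    Y <- with_seed(seed, tsne_exact(X, perplexity = perplexity,
                                    n_iter = n_iter))
    out <- data.frame(sample_id = ids, x = Y[, 1], y = Y[, 2])
    attr(out, "params") <- list(perplexity = perplexity, seed = seed,
                                n_iter = n_iter)
  }
  attr(out, "method") <- method
  class(out) <- c("embedding2d", "data.frame")
  out
}

# Exact t-SNE (van der Maaten & Hinton 2008): Gaussian input affinities with
# per-point bandwidths found by bisection on the perplexity, Student-t output
# kernel, gradient descent with momentum and early exaggeration. O(n^2).
tsne_exact <- function(X, perplexity = 30, n_iter = 500L, lr = 200,
                       momentum_start = 0.5, momentum_final = 0.8,
                       exaggeration = 4, exaggeration_iter = 100L) {
  n <- nrow(X)
  perplexity <- min(perplexity, (n - 1) / 3)
  D2 <- as.matrix(stats::dist(X))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      w <- exp(-d * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      H <- log(sw) + beta * sum(d * w) / sw
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  V <- matrix(0, n, 2)
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= exaggeration_iter) P * exaggeration else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) %*% Y - W %*% Y)
    mom <- if (it <= 250) momentum_start else momentum_final
    V <- mom * V - lr * grad
    Y <- Y + V
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Sampling-Shapley wavelength importance for a 1-D spectral model
#'
#' Monte-Carlo permutation estimate of Shapley values: for each evaluated
#' spectrum, random feature permutations are walked from a randomly drawn
#' background spectrum toward the evaluated one, crediting each wavelength
#' with its marginal change in the model output (probability of class 1).
#' Each permutation is paired with a single background draw, so per-sample
#' attributions satisfy additivity: they sum to `f(x)` minus the mean model
#' output over the drawn backgrounds. The reported profile is the global
#' mean absolute attribution per wavelength.
#'
#' @param model A trained `cnn1d` [build_cnn1d()] network, a
#'   `plsda_model`/`svm_model` baseline, or a function mapping a matrix of
#'   spectra (samples in rows) to a numeric model output.
#' @param spectra [spectrum_set()] of samples to explain.
#' @param background [spectrum_set()] of background (reference) spectra,
#'   typically drawn from the calibration set.
#' @param seed Seed for permutation and background draws.
#' @param n_perm Permutations per explained sample.
#' @return A list of class `importance_profile`: `importance` (mean absolute
#'   attribution per wavelength), `wavelengths_nm`, `attributions` (samples x
#'   wavelengths), `predicted_values`, `reference_values` (per-sample mean
#'   output of the drawn backgrounds), `method`, `background_size`.
#' @export
shap_wavelength_importance <- function(model, spectra, background,
                                       seed = 1L, n_perm = 10L) {
  if (n_samples(background) < 1L) stop("background set is empty")
  if (!isTRUE(all.equal(spectra$wavelengths_nm, background$wavelengths_nm)))
    stop("wavelength grids of spectra and background differ")
  f <- shap_value_fun(model, spectra)
  p <- n_wavelengths(spectra)
  ids <- spectra$sample_ids
  phi <- matrix(0, length(ids), p, dimnames = list(ids, NULL))
  fx <- numeric(length(ids)); fref <- numeric(length(ids))
  with_seed(seed, {
    for (s in seq_along(ids)) {
      x <- spectra$values[, s]
      contrib <- numeric(p)
      ref_sum <- 0
      for (r in seq_len(n_perm)) {
        z <- background$values[, sample.int(n_samples(background), 1)]
        perm <- sample.int(p)
        # walk z -> x along the permutation; row j has the first j features
        # (in perm order) taken from x
        M <- matrix(z, nrow = p + 1, ncol = p, byrow = TRUE)
        for (j in seq_len(p)) M[(j + 1):(p + 1), perm[j]] <- x[perm[j]]
        v <- f(M)
        contrib[perm] <- contrib[perm] + diff(v)
        ref_sum <- ref_sum + v[1]
      }
      phi[s, ] <- contrib / n_perm
      fref[s] <- ref_sum / n_perm
      fx[s] <- f(matrix(x, 1))
    }
  })
  structure(list(importance = colMeans(abs(phi)),
                 wavelengths_nm = spectra$wavelengths_nm,
                 attributions = phi,
                 predicted_values = fx,
                 reference_values = fref,
                 method = "permutation sampling Shapley",
                 background_size = n_samples(background),
                 n_perm = n_perm),
            class = "importance_profile")
}

shap_value_fun <- function(model, spectra) {
  if (is.function(model)) return(model)
  grid <- spectra$wavelengths_nm
  if (inherits(model, "gafnet")) {
    if (model$kind != "cnn1d") stop("SHAP wavelength importance needs a 1-D model")
    function(M) {
      ss <- spectrum_set(grid, t(M), sample_ids = as.character(seq_len(nrow(M))))
      as.numeric(predict(model, ss)$prob[, "class1"])
    }
  } else if (inherits(model, "baseline_model")) {
    function(M) as.numeric(predict(model, M)$prob[, "class1"])
  } else stop("unsupported model type for SHAP")
}

#' @export
print.importance_profile <- function(x, ...) {
  top <- order(-x$importance)[1:min(5, length(x$importance))]
  cat(sprintf("<importance_profile> %s over %d wavelengths (%d backgrounds)\n",
              x$method, length(x$importance), x$background_size))
  cat("top wavelengths (nm):", paste(round(x$wavelengths_nm[top], 1),
                                     collapse = ", "), "\n")
  invisible(x)
}

#' Write an embedding or importance profile as CSV
#' @param x An `embedding2d` or `importance_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interpretation <- function(x, path) {
  if (inherits(x, "embedding2d")) {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  } else if (inherits(x, "importance_profile")) {
    utils::write.csv(data.frame(wavelength_nm = x$wavelengths_nm,
                                mean_abs_attribution = x$importance),
                     path, row.names = FALSE)
  } else stop("unsupported object")
  invisible(path)
}
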