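#' Configuration for CARS wavelength selection
#'
#' Competitive adaptive reweighted sampling runs `n_mc_runs` Monte-Carlo
#' iterations. Each iteration fits a PLS regression of the 0/1 class response
#' on a random subset of samples, keeps the top wavelengths by absolute
#' regression coefficient according to an exponentially decreasing retention
#' schedule (run 1 retains every wavelength, the final run retains 2), then
#' resamples competitively among the survivors in proportion to those
#' coefficients. The subset with minimum cross-validated RMSE wins.
#'
#' @param n_mc_runs Number of Monte-Carlo runs (>= 2).
#' @param cv_folds Cross-validation folds for RMSECV (>= 2).
#' @param max_pls_components Cap on PLS latent components.
#' @param mc_sample_ratio Fraction of calibration samples drawn per run.
#' @param rng_seed Integer seed; selection is deterministic given the seed.
#' @return A list of class `cars_config` (includes the derived exponential
#'   decay constant `edf_k`).
#' @export
cars_config <- function(n_mc_runs = 50L, cv_folds = 5L,
                        max_pls_components = 10L, mc_sample_ratio = 0.8,
                        rng_seed = 1L) {
  if (n_mc_runs < 2L) stop("n_mc_runs must be >= 2")
  if (cv_folds < 2L) stop("cv_folds must be >= 2")
  if (mc_sample_ratio <= 0 || mc_sample_ratio > 1)
    stop("mc_sample_ratio must be in (0, 1]")
  structure(list(n_mc_runs = as.integer(n_mc_runs),
                 cv_folds = as.integer(cv_folds),
                 max_pls_components = as.integer(max_pls_components),
                 mc_sample_ratio = mc_sample_ratio,
                 rng_seed = as.integer(rng_seed)),
            class = "cars_config")
}

#' CARS feature-wavelength selection
#'
#' @param spectra A [spectrum_set()] in intensity mode.
#' @param labels A [label_table()]; the class is regressed as a 0/1 dummy.
#' @param config A [cars_config()].
#' @return A list of class `cars_selection` with `selected_indices`,
#'   `selected_wavelengths_nm`, `rmsecv_by_run`, `subset_size_by_run`,
#'   `best_run`, `subsets_by_run` and the `config` used.
#' @export
cars_select <- function(spectra, labels, config = cars_config()) {
  stopifnot(inherits(config, "cars_config"))
  if (spectra$mode != "intensity")
    stop("CARS operates on intensity-mode spectra")
  X <- t(spectra$values)
  y <- as.numeric(labels_for(spectra, labels) == "class2")
  n <- nrow(X); p <- ncol(X)
  if (min(table(y)) < 2L * config$cv_folds)
    stop("need at least 2 * cv_folds samples per class")
  if (max(abs(sweep(X, 2, X[1, ]))) == 0)
    stop("degenerate input: all spectra identical")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$rng_seed)

  N <- config$n_mc_runs
  edf_k <- log(p / 2) / (N - 1)       # run 1 -> p variables, run N -> 2
  keep_n <- pmin(p, ceiling(p * exp(-edf_k * (seq_len(N) - 1))))
  keep_n[N] <- 2L
  fold_id <- sample(rep_len(seq_len(config$cv_folds), n))  # one partition for all runs

  subset <- seq_len(p)
  subsets <- vector("list", N)
  rmsecv <- numeric(N)
  sizes <- integer(N)
  for (run in seq_len(N)) {
    mc <- sort(sample(n, max(2L, round(config$mc_sample_ratio * n))))
    ncomp <- min(config$max_pls_components, length(subset), length(mc) - 1L)
    fit <- simpls_fit(X[mc, subset, drop = FALSE], y[mc], ncomp)
    w <- abs(fit$coef[, fit$ncomp])
    k_target <- min(keep_n[run], length(subset))
    if (run == 1L) {
      new_subset <- subset                       # full grid evaluated first
    } else {
      # competitive (forced) retention of the top-|b| wavelengths;
      # ties broken toward the lower wavelength index
      keep_ord <- order(-w, seq_along(subset))[seq_len(k_target)]
      survivors <- subset[sort(keep_ord)]
      w_s <- w[sort(keep_ord)]
      if (all(w_s == 0)) stop("degenerate coefficients: no class signal to rank")
      # adaptive reweighted sampling among survivors
      draw <- sample(seq_along(survivors), size = k_target, replace = TRUE,
                     prob = w_s)
      new_subset <- survivors[sort(unique(draw))]
      if (length(new_subset) < 2L) new_subset <- survivors
    }
    subset <- new_subset
    cv <- pls_rmsecv(X[, subset, drop = FALSE], y, fold_id,
                     config$max_pls_components)
    subsets[[run]] <- subset
    rmsecv[run] <- cv$rmsecv
    sizes[run] <- length(subset)
  }
  best <- which.min(rmsecv)
  sel <- subsets[[best]]
  structure(list(selected_indices = sel,
                 selected_wavelengths_nm = spectra$wavelengths_nm[sel],
                 rmsecv_by_run = rmsecv,
                 subset_size_by_run = sizes,
                 best_run = best,
                 subsets_by_run = subsets,
                 config = config),
            class = "cars_selection")
}

#' @export
print.cars_selection <- function(x, ...) {
  cat(sprintf(
    "<cars_selection> %d wavelengths selected at run %d (RMSECV %.4f) of %d runs\n",
    length(x$selected_indices), x$best_run, x$rmsecv_by_run[x$best_run],
    length(x$rmsecv_by_run)))
  invisible(x)
}

#' @export
plot.cars_selection <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(x$subset_size_by_run, type = "s", xlab = "run",
                 ylab = "subset size", ...)
  graphics::plot(x$rmsecv_by_run, type = "b", xlab = "run", ylab = "RMSECV",
                 ...)
  graphics::abline(v = x$best_run, lty = 2)
  invisible(x)
}

#' Serialize a CARS selection to JSON
#' @param selection A [cars_select()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(selection, path) {
  jsonlite::write_json(
    list(selected_indices = selection$selected_indices,
         selected_wavelengths_nm = selection$selected_wavelengths_nm,
         rmsecv_by_run = selection$rmsecv_by_run,
         subset_size_by_run = selection$subset_size_by_run,
         best_run = selection$best_run),
    path, digits = NA)
  invisible(path)
}

#' Restrict a spectrum set to selected wavelengths
#'
#' @param spectra A [spectrum_set()].
#' @param selection A [cars_select()] result or an integer index vector.
#' @return A `spectrum_set` on the selected wavelengths, original order
#'   preserved.
#' @export
restrict_spectra <- function(spectra, selection) {
  idx <- if (inherits(selection, "cars_selection")) selection$selected_indices
         else as.integer(selection)
  if (!length(idx)) stop("empty wavelength selection")
  if (any(idx < 1L | idx > n_wavelengths(spectra)))
    stop("selection indices outside the wavelength grid")
  idx <- sort(unique(idx))
  spectrum_set(spectra$wavelengths_nm[idx],
               spectra$values[idx, , drop = FALSE],
               sample_ids = spectra$sample_ids, mode = spectra$mode)
}
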