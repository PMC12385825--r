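#' Kennard-Stone calibration/prediction split
#'
#' Deterministic max-min-distance sample selection, applied independently
#' within each class (the printed class counts of a 3:1 design, e.g.
#' 163 -> 122 + 41 and 160 -> 120 + 40, correspond to per-class application).
#' Within a class the calibration set is seeded with the two mutually most
#' distant spectra (Euclidean distance on the raw value vectors), then grown
#' by repeatedly adding the sample whose minimum distance to the chosen set
#' is largest, until the quota `floor(ratio * n / (ratio + 1))` is reached.
#' Distance ties are broken by sample order, so the split is reproducible.
#'
#' @param spectra A [spectrum_set()].
#' @param labels A [label_table()] covering every sample (ignored when
#'   `per_class = FALSE`).
#' @param ratio Target calibration:prediction ratio (default 3, i.e. 3:1).
#' @param per_class Apply the algorithm within each class (default TRUE).
#' @return A list of class `ks_split` with `calibration_ids`,
#'   `prediction_ids`, `ratio` and `per_class`.
#' @export
kennard_stone_split <- function(spectra, labels = NULL, ratio = 3,
                                per_class = TRUE) {
  if (anyDuplicated(spectra$sample_ids)) stop("duplicate sample ids")
  groups <- if (per_class) {
    if (is.null(labels)) stop("labels required for a per-class split")
    lab <- labels_for(spectra, labels)
    split(spectra$sample_ids, lab)
  } else list(all = spectra$sample_ids)
  cal <- character(0)
  for (ids in groups) {
    if (!length(ids)) next
    cal <- c(cal, ks_pick(spectra$values[, ids, drop = FALSE],
                          quota = floor(ratio * length(ids) / (ratio + 1))))
  }
  cal <- spectra$sample_ids[spectra$sample_ids %in% cal]
  structure(list(calibration_ids = cal,
                 prediction_ids = setdiff(spectra$sample_ids, cal),
                 ratio = ratio, per_class = per_class),
            class = "ks_split")
}

#' @export
print.ks_split <- function(x, ...) {
  cat(sprintf("<ks_split> %d calibration / %d prediction (ratio %g:1%s)\n",
              length(x$calibration_ids), length(x$prediction_ids), x$ratio,
              if (x$per_class) ", per class" else ""))
  invisible(x)
}

# max-min selection of `quota` column names of X
ks_pick <- function(X, quota) {
  ids <- colnames(X)
  n <- ncol(X)
  if (n < 2L) stop("need at least 2 samples per group")
  quota <- max(2L, min(quota, n))
  D <- as.matrix(stats::dist(t(X)))
  # seed: mutually most distant pair, first such pair in sample order
  w <- which(D == max(D), arr.ind = TRUE)
  w <- w[w[, 1] < w[, 2], , drop = FALSE]
  w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
  chosen <- c(w[1, 1], w[1, 2])
  mind <- pmin(D[, chosen[1]], D[, chosen[2]])
  while (length(chosen) < quota) {
    mind[chosen] <- -Inf
    nxt <- which.max(mind)            # ties: lowest index, i.e. sample order
    chosen <- c(chosen, nxt)
    mind <- pmin(mind, D[, nxt])
  }
  ids[sort(chosen)]
}
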