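#' Configuration for the synthetic transmittance-cohort generator
#'
#' The generator emulates two-cultivar fruit transmittance spectra on the
#' 630-1000 nm grid (501 points): every spectrum is a per-sample brightness
#' factor times a smooth shape -- two Gaussian transmission peaks near 715 and
#' 800 nm on a slowly varying baseline -- plus additive detector noise. Class
#' structure enters in two ways that mirror the real phenomenon: class 1 is
#' systematically dimmer overall (brightness ratio `class_intensity_ratio`),
#' and the relative height of the 800 nm peak differs slightly between
#' classes (`peak_height_ratio`), so that classifiers which see only the
#' per-spectrum-normalized shape still have signal. Optional planted
#' discriminative bands (`informative_band_indices`) multiply class-2 values
#' at those wavelengths only.
#'
#' @param n_per_class Integer vector of length 2: samples per class.
#' @param grid_start_nm,grid_stop_nm,n_points Wavelength grid (defaults
#'   630-1000 nm, 501 points).
#' @param peak_centers_nm Centres of the two transmission peaks (nm).
#' @param peak_widths_nm Gaussian SD of each peak (nm).
#' @param base_intensity Mean detector counts of class 1 at the main peak.
#' @param class_intensity_ratio Mean overall-brightness ratio class2/class1
#'   (> 1 means class 1 is dimmer).
#' @param within_class_cv Log-scale SD of the per-sample brightness factor
#'   (size/rind variability).
#' @param peak_height_ratio Length-2 vector: mean height of the second peak
#'   relative to the first, per class.
#' @param peak_ratio_sd Within-class SD of that relative height.
#' @param noise_sd Additive noise SD as a fraction of `base_intensity`.
#' @param informative_band_indices Optional integer indices where class 2 is
#'   multiplied by `1 + informative_contrast`.
#' @param informative_contrast Relative contrast planted at those indices.
#' @param rng_seed Integer seed; the cohort is fully reproducible from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_class = c(100L, 100L),
                             grid_start_nm = 630, grid_stop_nm = 1000,
                             n_points = 501L,
                             peak_centers_nm = c(715, 800),
                             peak_widths_nm = c(30, 45),
                             base_intensity = 1000,
                             class_intensity_ratio = 1.3,
                             within_class_cv = 0.2,
                             peak_height_ratio = c(0.84, 0.96),
                             peak_ratio_sd = 0.02,
                             noise_sd = 0.02,
                             informative_band_indices = NULL,
                             informative_contrast = 0.2,
                             rng_seed = 1L) {
  if (any(n_per_class <= 0)) stop("n_per_class must be positive")
  if (n_points < 2L) stop("need at least 2 grid points")
  if (class_intensity_ratio <= 0) stop("class_intensity_ratio must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic two-class cohort
#'
#' @param config A [synthetic_config()].
#' @return A list with `spectra` (a [spectrum_set()] in intensity mode,
#'   strictly positive values) and `labels` (a [label_table()]); sample ids
#'   are `C1_###` / `C2_###`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  wl <- seq(cf$grid_start_nm, cf$grid_stop_nm, length.out = cf$n_points)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cf$rng_seed)

  baseline <- 0.12 + 0.08 * exp(-((wl - 850) / 180)^2)
  peak <- function(center, width) exp(-((wl - center)^2) / (2 * width^2))
  p1 <- peak(cf$peak_centers_nm[1], cf$peak_widths_nm[1])
  p2 <- peak(cf$peak_centers_nm[2], cf$peak_widths_nm[2])

  n1 <- cf$n_per_class[1]; n2 <- cf$n_per_class[2]
  ids <- c(sprintf("C1_%03d", seq_len(n1)), sprintf("C2_%03d", seq_len(n2)))
  cls <- rep(c("class1", "class2"), c(n1, n2))
  scale_c <- c(class1 = cf$base_intensity,
               class2 = cf$base_intensity * cf$class_intensity_ratio)
  ratio_c <- c(class1 = cf$peak_height_ratio[1], class2 = cf$peak_height_ratio[2])

  vals <- matrix(0, cf$n_points, n1 + n2)
  for (j in seq_along(ids)) {
    c_j <- cls[j]
    brightness <- scale_c[[c_j]] * exp(stats::rnorm(1, 0, cf$within_class_cv))
    h2 <- ratio_c[[c_j]] + stats::rnorm(1, 0, cf$peak_ratio_sd)
    shape <- baseline + p1 + h2 * p2
    if (c_j == "class2" && length(cf$informative_band_indices))
      shape[cf$informative_band_indices] <-
        shape[cf$informative_band_indices] * (1 + cf$informative_contrast)
    v <- brightness * shape +
      stats::rnorm(cf$n_points, 0, cf$noise_sd * cf$base_intensity)
    vals[, j] <- pmax(v, 1e-3 * cf$base_intensity)  # detector floor: keep counts positive
  }
  list(spectra = spectrum_set(wl, vals, sample_ids = ids, mode = "intensity"),
       labels = label_table(ids, cls))
}
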