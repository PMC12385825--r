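#' Spectrum sets
#'
#' A `spectrum_set` holds per-sample VIS-NIR spectra measured on one shared,
#' strictly increasing wavelength grid. Values are either raw transmittance
#' intensities (detector counts) or absorbance units.
#'
#' @param wavelengths_nm Numeric vector, strictly increasing wavelength grid
#'   in nanometres.
#' @param values Numeric matrix, one row per wavelength and one column per
#'   sample.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to the column names of `values`.
#' @param mode Either `"intensity"` or `"absorbance"`.
#'
#' @return An object of class `spectrum_set`: a list with elements
#'   `wavelengths_nm`, `values`, `sample_ids` and `mode`.
#' @export
spectrum_set <- function(wavelengths_nm, values, sample_ids = colnames(values),
                         mode = c("intensity", "absorbance")) {
  mode <- match.arg(mode)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("spectral values must be numeric")
  if (anyNA(wavelengths_nm) || anyNA(values)) stop("spectra contain missing values")
  if (length(wavelengths_nm) < 1L) stop("empty wavelength grid")
  if (is.unsorted(wavelengths_nm, strictly = TRUE))
    stop("wavelength grid must be strictly increasing")
  if (nrow(values) != length(wavelengths_nm))
    stop("values must have one row per wavelength (got ", nrow(values),
         " rows for ", length(wavelengths_nm), " wavelengths)")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != ncol(values)) stop("one sample id per column required")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  colnames(values) <- sample_ids
  structure(list(wavelengths_nm = wavelengths_nm, values = values,
                 sample_ids = sample_ids, mode = mode),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d samples x %d wavelengths (%.4g-%.4g nm), mode = %s\n",
              ncol(x$values), length(x$wavelengths_nm),
              min(x$wavelengths_nm), max(x$wavelengths_nm), x$mode))
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$values)

n_samples <- function(x) ncol(x$values)
n_wavelengths <- function(x) nrow(x$values)

#' Subset a spectrum set by sample id
#'
#' @param spectra A [spectrum_set()].
#' @param ids Character vector of sample ids to keep (order preserved).
#' @return A `spectrum_set` with the requested samples.
#' @export
subset_samples <- function(spectra, ids) {
  missing <- setdiff(ids, spectra$sample_ids)
  if (length(missing)) stop("unknown sample ids: ", paste(missing, collapse = ", "))
  spectrum_set(spectra$wavelengths_nm, spectra$values[, ids, drop = FALSE],
               sample_ids = ids, mode = spectra$mode)
}

#' Read spectra from a wide CSV
#'
#' The expected layout is one wavelength per row: the first column (named
#' `wavelength_nm`) holds the grid and every further column is one sample.
#'
#' @param path Path to a UTF-8, comma-separated file.
#' @param mode Measurement mode of the stored values.
#' @return A [spectrum_set()].
#' @export
read_spectra <- function(path, mode = c("intensity", "absorbance")) {
  mode <- match.arg(mode)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("spectra CSV needs a wavelength column plus >= 1 sample column")
  num <- suppressWarnings(lapply(df, as.numeric))
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]) & !is.na(df[[j]]) & nzchar(df[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d, column '%s'", bad[1],
                   names(df)[j]))
    if (anyNA(num[[j]]))
      stop(sprintf("missing value in column '%s'", names(df)[j]))
  }
  wl <- num[[1]]
  vals <- do.call(cbind, num[-1])
  colnames(vals) <- names(df)[-1]
  spectrum_set(wl, vals, mode = mode)
}

#' Write spectra to a wide CSV
#'
#' Inverse of [read_spectra()]; values are written at full precision so a
#' write/read round trip is exact.
#'
#' @param spectra A [spectrum_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  df <- data.frame(wavelength_nm = format(spectra$wavelengths_nm, digits = 17,
                                          trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (id in spectra$sample_ids)
    df[[id]] <- format(spectra$values[, id], digits = 17, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample label table
#'
#' @param path CSV with columns `sample_id` and `label`; labels must take
#'   exactly the two values `class1` and `class2` (class1 is the positive
#'   class throughout the package, e.g. the seedless cultivar).
#' @return A data frame with `sample_id` (character) and `label` (factor with
#'   levels `class1`, `class2`).
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  label_table(df$sample_id, df$label)
}

#' Build a label table
#'
#' @param sample_id Character vector of sample ids.
#' @param label Vector of class labels, values in `{class1, class2}`.
#' @return Data frame with columns `sample_id`, `label`.
#' @export
label_table <- function(sample_id, label) {
  if (is.null(sample_id) || is.null(label)) stop("sample_id and label required")
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in label table")
  label <- as.character(label)
  bad <- setdiff(unique(label), c("class1", "class2"))
  if (length(bad)) stop("labels must be 'class1' or 'class2'; got: ",
                        paste(bad, collapse = ", "))
  data.frame(sample_id = sample_id,
             label = factor(label, levels = c("class1", "class2")),
             stringsAsFactors = FALSE)
}

#' Write a label table to CSV
#' @param labels A label table from [label_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(data.frame(sample_id = labels$sample_id,
                              label = as.character(labels$label)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# labels aligned to the sample order of a spectrum_set
labels_for <- function(spectra, labels) {
  i <- match(spectra$sample_ids, labels$sample_id)
  if (anyNA(i)) stop("labels missing for samples: ",
                     paste(spectra$sample_ids[is.na(i)], collapse = ", "))
  labels$label[i]
}

#' Convert raw transmittance intensities to absorbance
#'
#' Absorbance is \eqn{-\log_{10}((I - I_B) / (I_R - I_B))}, where \eqn{I} is
#' the sample intensity, \eqn{I_B} the background (light off) and \eqn{I_R}
#' the reference standard, all on one wavelength grid.
#'
#' @param sample A [spectrum_set()] of intensity spectra.
#' @param background Single-sample `spectrum_set` (or numeric vector) of
#'   background intensities.
#' @param reference Single-sample `spectrum_set` (or numeric vector) of
#'   reference intensities; `reference - background` must be strictly
#'   positive everywhere.
#' @return A `spectrum_set` in absorbance mode.
#' @export
compute_absorbance <- function(sample, background, reference) {
  if (sample$mode != "intensity") stop("sample spectra must be in intensity mode")
  bg <- spectrum_values(background, sample)
  ref <- spectrum_values(reference, sample)
  denom <- ref - bg
  if (any(denom <= 0))
    stop(sprintf("reference minus background is non-positive at %.4g nm",
                 sample$wavelengths_nm[which(denom <= 0)[1]]))
  num <- sample$values - bg
  if (any(num <= 0)) {
    bad <- which(num <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "intensity does not exceed background at %.4g nm (sample '%s'); absorbance undefined",
      sample$wavelengths_nm[bad[1]], sample$sample_ids[bad[2]]))
  }
  spectrum_set(sample$wavelengths_nm, -log10(num / denom),
               sample_ids = sample$sample_ids, mode = "absorbance")
}

# coerce a background/reference argument to a numeric vector on `like`'s grid
spectrum_values <- function(x, like) {
  if (inherits(x, "spectrum_set")) {
    if (!isTRUE(all.equal(x$wavelengths_nm, like$wavelengths_nm)))
      stop("wavelength grids differ")
    if (ncol(x$values) != 1L) stop("expected a single-sample spectrum")
    return(as.numeric(x$values[, 1]))
  }
  x <- as.numeric(x)
  if (length(x) != length(like$wavelengths_nm))
    stop("length does not match the wavelength grid")
  x
}
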