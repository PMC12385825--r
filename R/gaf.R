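#' Min-max normalize a spectrum to the unit interval
#'
#' Maps a sequence linearly so its minimum becomes 0 and its maximum 1; this
#' is the scaling step that precedes the polar (angular) encoding, and it
#' deliberately removes overall brightness and offset from each spectrum.
#'
#' @param values Numeric vector with at least two points and non-zero range.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_spectrum <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 points to normalize")
  if (anyNA(values)) stop("values contain NA")
  rng <- range(values)
  if (rng[2] <= rng[1])
    stop("degenerate spectrum: constant values have zero range")
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Polar (angular) encoding of a normalized spectrum
#'
#' Each normalized value \eqn{\tilde x_i \in [0,1]} becomes an angle
#' \eqn{\alpha_i = \arccos(\tilde x_i) \in [0, \pi/2]}; the point index
#' becomes a radius \eqn{r_i = i/n}. An intensity of 1 therefore maps to a
#' polar angle of 0 degrees and an intensity of 0 to 90 degrees. The radius
#' is carried along for polar plots only; the Gramian matrices use the
#' angles alone.
#'
#' @param normalized Numeric vector with all values in `[0, 1]`.
#' @return A list of class `polar_encoding` with elements `normalized`,
#'   `angles_rad`, `radii` and `n`.
#' @export
to_polar <- function(normalized) {
  normalized <- as.numeric(normalized)
  if (anyNA(normalized)) stop("values contain NA")
  tol <- 1e-12
  if (any(normalized < -tol | normalized > 1 + tol))
    stop("normalized values must lie in [0, 1]")
  normalized <- pmin(pmax(normalized, 0), 1)
  n <- length(normalized)
  structure(list(normalized = normalized,
                 angles_rad = acos(normalized),
                 radii = seq_len(n) / n,
                 n = n),
            class = "polar_encoding")
}

#' Gramian Angular Summation Field matrix
#'
#' Entry \eqn{(m,k)} is \eqn{\cos(\alpha_m + \alpha_k)}: symmetric, entries
#' in `[-1, 1]`, diagonal \eqn{2\tilde x_i^2 - 1}. Index 1 (the first
#' wavelength) sits at the top-left of the matrix.
#'
#' @param polar A [to_polar()] encoding.
#' @return An `n x n` numeric matrix.
#' @export
gasf_matrix <- function(polar) {
  stopifnot(inherits(polar, "polar_encoding"))
  a <- polar$angles_rad
  cos(outer(a, a, `+`))
}

#' Gramian Angular Difference Field matrix
#'
#' Entry \eqn{(m,k)} is \eqn{\sin(\alpha_m - \alpha_k)}: antisymmetric with a
#' zero diagonal.
#'
#' @param polar A [to_polar()] encoding.
#' @return An `n x n` numeric matrix.
#' @export
gadf_matrix <- function(polar) {
  stopifnot(inherits(polar, "polar_encoding"))
  a <- polar$angles_rad
  sin(outer(a, a, `-`))
}

#' GASF/GADF pair for one spectrum
#'
#' Normalizes the raw values, applies the polar encoding and returns both
#' Gramian matrices.
#'
#' @param values Raw (or already normalized) numeric spectrum.
#' @return A list of class `gaf_pair` with elements `gasf`, `gadf`, `polar`
#'   and `n`.
#' @export
gaf_pair <- function(values) {
  polar <- to_polar(normalize_spectrum(values))
  structure(list(gasf = gasf_matrix(polar), gadf = gadf_matrix(polar),
                 polar = polar, n = polar$n),
            class = "gaf_pair")
}

#' @export
print.gaf_pair <- function(x, ...) {
  cat(sprintf("<gaf_pair> %d x %d GASF/GADF matrices\n", x$n, x$n))
  invisible(x)
}

# Bilinear resampling of a matrix onto a `size x size` grid with exact corner
# alignment (output corners coincide with input corners), so an n -> n resize
# is the identity.
resize_bilinear <- function(mat, size) {
  n_r <- nrow(mat); n_c <- ncol(mat)
  if (size == n_r && size == n_c) return(mat)
  map_axis <- function(n_in) {
    if (n_in == 1L) {
      list(lo = rep(1L, size), hi = rep(1L, size), w = rep(0, size))
    } else {
      pos <- seq(0, n_in - 1, length.out = size)
      lo <- pmin(floor(pos), n_in - 2)
      list(lo = as.integer(lo) + 1L, hi = as.integer(lo) + 2L, w = pos - lo)
    }
  }
  r <- map_axis(n_r); cc <- map_axis(n_c)
  a <- mat[r$lo, cc$lo, drop = FALSE]; b <- mat[r$hi, cc$lo, drop = FALSE]
  d <- mat[r$lo, cc$hi, drop = FALSE]; e <- mat[r$hi, cc$hi, drop = FALSE]
  wr <- r$w; wc <- cc$w
  top <- a * (1 - wr) + b * wr
  bot <- d * (1 - wr) + e * wr
  top * rep(1 - wc, each = size) + bot * rep(wc, each = size)
}

gaf_colormap <- function(name = "viridis", n = 256L) {
  grDevices::col2rgb(grDevices::hcl.colors(n, palette = name))
}

#' Render a Gramian matrix as a 3-channel 8-bit image
#'
#' The matrix is first resampled bilinearly to `size x size`, then mapped
#' linearly from `[-1, 1]` through a perceptual colormap to RGB. Matrix row 1
#' / column 1 (the first wavelength) becomes the top-left pixel. The result
#' is deterministic for fixed inputs.
#'
#' @param mat Numeric matrix with entries in `[-1, 1]` (a GASF or GADF).
#' @param size Output side length in pixels (default 300, giving the
#'   `300 x 300 x 3` network input).
#' @param colormap Palette name understood by [grDevices::hcl.colors()]
#'   (default `"viridis"`).
#' @param source Which Gramian field the matrix is (metadata only).
#' @return A `gaf_image`: an integer `size x size x 3` array in `[0, 255]`
#'   with attributes `colormap` and `source`.
#' @export
render_gaf_image <- function(mat, size = 300L, colormap = "viridis",
                             source = c("gasf", "gadf")) {
  source <- match.arg(source)
  mat <- as.matrix(mat)
  if (size < 2L) stop("image size must be at least 2")
  tol <- 1e-9
  if (any(mat < -1 - tol | mat > 1 + tol))
    stop("matrix entries must lie in [-1, 1]")
  mat <- pmin(pmax(mat, -1), 1)
  rs <- resize_bilinear(mat, as.integer(size))
  pal <- gaf_colormap(colormap)
  n_col <- ncol(pal)
  idx <- pmin(pmax(floor((rs + 1) / 2 * n_col) + 1, 1), n_col)
  px <- array(0L, dim = c(size, size, 3L))
  for (ch in 1:3) px[, , ch] <- matrix(as.integer(pal[ch, idx]), size, size)
  structure(px, class = "gaf_image", colormap = colormap, source = source)
}

#' @export
print.gaf_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<gaf_image> %d x %d x %d (%s, colormap '%s')\n",
              d[1], d[2], d[3], attr(x, "source"), attr(x, "colormap")))
  invisible(x)
}

#' Write a GAF image as PNG with a JSON sidecar
#'
#' @param image A [render_gaf_image()] result.
#' @param path Output `.png` path; a `.json` sidecar recording the sample id,
#'   source field, colormap, size, and wavelength subset is written next to it.
#' @param sample_id,wavelengths_nm Optional metadata recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_gaf_png <- function(image, path, sample_id = NULL, wavelengths_nm = NULL) {
  stopifnot(inherits(image, "gaf_image"))
  arr <- unclass(image) / 255
  png::writePNG(arr, path)
  meta <- list(sample_id = sample_id, source = attr(image, "source"),
               colormap = attr(image, "colormap"), size = dim(image)[1],
               wavelengths_nm = wavelengths_nm)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       sub("\\.png$", ".json", path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Encode every sample of a spectrum set as GASF/GADF image arrays
#'
#' Convenience wrapper used by the model-training pipeline: each spectrum is
#' normalized (per spectrum, over whatever wavelength subset it carries),
#' polar-encoded, converted to both Gramian matrices and rendered at the
#' requested size.
#'
#' @param spectra A [spectrum_set()].
#' @param size Image side length in pixels.
#' @param colormap Palette name.
#' @return A list with `gasf` and `gadf`: each a list (one per sample) of
#'   `size x size x 3` numeric arrays scaled to `[0, 1]`, named by sample id.
#' @export
encode_gaf_images <- function(spectra, size = 300L, colormap = "viridis") {
  enc <- function(id, which) {
    pair <- gaf_pair(spectra$values[, id])
    img <- render_gaf_image(pair[[which]], size = size, colormap = colormap,
                            source = which)
    unclass(img) / 255
  }
  ids <- spectra$sample_ids
  list(gasf = stats::setNames(lapply(ids, enc, which = "gasf"), ids),
       gadf = stats::setNames(lapply(ids, enc, which = "gadf"), ids))
}
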