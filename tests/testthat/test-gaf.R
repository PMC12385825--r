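test_that("min-max normalization maps endpoints and preserves order", {
  expect_equal(normalize_spectrum(c(1, 2, 3)), c(0, 0.5, 1))
  set.seed(11)
  v <- rnorm(40, sd = 5)
  x <- normalize_spectrum(v)
  expect_equal(x[which.min(v)], 0)
  expect_equal(x[which.max(v)], 1)
  expect_identical(order(x), order(v))
  expect_error(normalize_spectrum(c(5, 5, 5)), "zero range")
  expect_error(normalize_spectrum(3), "at least 2")
})

test_that("polar encoding maps intensities to angles in [0, 90] degrees", {
  pe <- to_polar(c(1, 0, 0.5))
  expect_equal(pe$angles_rad, c(0, pi / 2, pi / 3))
  expect_equal(pe$radii, c(1, 2, 3) / 3)
  expect_error(to_polar(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("GASF/GADF satisfy the closed-form identities and symmetries", {
  set.seed(21)
  for (rep in 1:10) {
    v <- rnorm(25)
    x <- normalize_spectrum(v)
    pe <- to_polar(x)
    G <- gasf_matrix(pe)
    D <- gadf_matrix(pe)
    s <- sqrt(1 - x^2)
    expect_lt(max(abs(G - (outer(x, x) - outer(s, s)))), 1e-12)
    expect_lt(max(abs(D - (outer(s, x) - outer(x, s)))), 1e-12)
    expect_equal(G, t(G))
    expect_equal(D, -t(D))
    expect_equal(diag(D), rep(0, 25))
    expect_equal(diag(G), 2 * x^2 - 1)
    expect_true(all(G >= -1 - 1e-12 & G <= 1 + 1e-12))
    expect_true(all(D >= -1 - 1e-12 & D <= 1 + 1e-12))
  }
})

test_that("encoding is invariant to affine rescaling of the raw spectrum", {
  set.seed(5)
  v <- rnorm(30)
  p1 <- gaf_pair(v)
  p2 <- gaf_pair(3.7 * v + 42)
  expect_equal(p1$gasf, p2$gasf)
  expect_equal(p1$gadf, p2$gadf)
})

test_that("image rendering resamples, colormaps and stays deterministic", {
  set.seed(3)
  G <- gaf_pair(rnorm(50))$gasf
  img <- render_gaf_image(G, size = 30)
  expect_s3_class(img, "gaf_image")
  expect_equal(dim(img), c(30L, 30L, 3L))
  expect_true(all(img >= 0 & img <= 255))
  expect_identical(unclass(img), unclass(render_gaf_image(G, size = 30)))

  # identity resize: pixel (i, j) is the colormap of entry (i, j)
  small <- matrix(c(-1, 0, 0.5, 1), 2, 2)
  im2 <- render_gaf_image(small, size = 2)
  pal <- grDevices::col2rgb(grDevices::hcl.colors(256, "viridis"))
  expect_equal(as.integer(im2[2, 2, ]), as.integer(pal[, 256]))
  expect_equal(as.integer(im2[1, 1, ]), as.integer(pal[, 1]))

  # constant +1 matrix -> every pixel is the palette's top colour
  ones <- matrix(1, 5, 5)
  im3 <- render_gaf_image(ones, size = 4)
  expect_true(all(apply(im3, 3, function(ch) length(unique(c(ch)))) == 1))
  expect_equal(as.integer(im3[1, 1, ]), as.integer(pal[, 256]))

  expect_error(render_gaf_image(matrix(2, 3, 3), 4), "\\[-1, 1\\]")
})

test_that("the first wavelength encodes at the top-left of matrix and image", {
  v <- c(10, rep(1, 39))            # spike at the first wavelength
  pair <- gaf_pair(v)
  expect_equal(which(pair$gasf == max(pair$gasf), arr.ind = TRUE)[1, ],
               c(row = 1, col = 1))
  rs <- gaffuse:::resize_bilinear(pair$gasf, 20)
  expect_equal(which(rs == max(rs), arr.ind = TRUE)[1, ], c(row = 1, col = 1))
})

test_that("PNG export writes the image and a metadata sidecar", {
  g <- gaf_pair(sin(seq(0, 4, length.out = 30)))
  img <- render_gaf_image(g$gadf, size = 12, source = "gadf")
  path <- withr::local_tempfile(fileext = ".png")
  write_gaf_png(img, path, sample_id = "S1", wavelengths_nm = 1:30)
  expect_true(file.exists(path))
  px <- png::readPNG(path)
  expect_equal(dim(px), c(12, 12, 3))
  expect_equal(round(px * 255), unclass(img), ignore_attr = TRUE)
  meta <- jsonlite::read_json(sub("\\.png$", ".json", path))
  expect_equal(meta$source, "gadf")
  expect_equal(meta$sample_id, "S1")
})
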