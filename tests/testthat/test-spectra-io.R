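test_that("wide CSV parsing builds a validated spectrum set", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,S001,S002",
               "630,100,110", "630.74,101,111", "631.48,99,112"), path)
  ss <- read_spectra(path)
  expect_s3_class(ss, "spectrum_set")
  expect_equal(dim(ss), c(3L, 2L))
  expect_equal(ss$sample_ids, c("S001", "S002"))
  expect_equal(ss$values[, "S002"], c(110, 111, 112), ignore_attr = TRUE)

  writeLines(c("wavelength_nm,S001", "700,1", "650,2"), path)
  expect_error(read_spectra(path), "strictly increasing")

  writeLines(c("wavelength_nm,S001", "630,1", "631,abc"), path)
  expect_error(read_spectra(path), "row 2, column 'S001'")
})

test_that("write/read round trip preserves values at full precision", {
  co <- small_cohort(n = 3, n_points = 20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(co$spectra, path)
  back <- read_spectra(path)
  expect_identical(back$values, co$spectra$values)
  expect_identical(back$wavelengths_nm, co$spectra$wavelengths_nm)

  lpath <- withr::local_tempfile(fileext = ".csv")
  write_labels(co$labels, lpath)
  expect_identical(read_labels(lpath), co$labels)
})

test_that("spectrum_set enforces its invariants", {
  expect_error(spectrum_set(c(2, 1), matrix(1:4, 2)), "strictly increasing")
  expect_error(spectrum_set(1:3, matrix(1:4, 2)), "one row per wavelength")
  expect_error(spectrum_set(1:2, matrix(1:4, 2),
                            sample_ids = c("a", "a")), "duplicate")
  expect_error(label_table(c("a", "b"), c("class1", "weird")), "class1")
})

test_that("absorbance follows -log10 of background-corrected transmittance", {
  wl <- c(630, 700, 800)
  ref <- c(1000, 1200, 1100)
  bg <- c(50, 60, 55)
  # sample equal to the reference -> absorbance identically zero
  s_ref <- spectrum_set(wl, cbind(A = ref))
  out <- compute_absorbance(s_ref, bg, ref)
  expect_equal(unname(out$values[, 1]), c(0, 0, 0))
  expect_identical(out$mode, "absorbance")

  # 10% relative transmittance -> absorbance exactly 1
  s_ten <- spectrum_set(wl, cbind(A = bg + 0.1 * (ref - bg)))
  expect_equal(unname(compute_absorbance(s_ten, bg, ref)$values[, 1]),
               rep(1, 3))

  # monotone decreasing in intensity
  s_lo <- spectrum_set(wl, cbind(A = ref * 0.5))
  s_hi <- spectrum_set(wl, cbind(A = ref * 0.8))
  expect_true(all(compute_absorbance(s_lo, bg, ref)$values >
                    compute_absorbance(s_hi, bg, ref)$values))

  # intensity at/below background is a domain error naming the wavelength
  bad <- spectrum_set(wl, cbind(A = c(1000, 40, 1100)))
  expect_error(compute_absorbance(bad, bg, ref), "700")
  expect_error(compute_absorbance(s_ref, ref, bg), "non-positive")
})
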