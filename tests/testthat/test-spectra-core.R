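test_that("spectrum construction enforces grid and sign invariants", {
  expect_s3_class(spectrum(300:310, rep(1, 11), "emission"), "spectrum")
  expect_error(spectrum(c(300, 300, 301), c(1, 2, 3), "emission"),
               "strictly increasing")
  expect_error(spectrum(c(302, 301, 300), c(1, 2, 3), "emission"),
               "strictly increasing")
  expect_error(spectrum(300, 1, "emission"), "at least 2")
  expect_error(spectrum(300:302, 1:2, "emission"), "lengths differ")
  expect_error(spectrum(300:302, c(1, -1, 2), "absorbance"),
               "non-negative")
  # CD values may be negative
  expect_s3_class(spectrum(200:210, seq(-20, 10, length.out = 11), "cd"),
                  "spectrum")
})

test_that("intensity_at interpolates linearly, exactly at grid points", {
  s <- spectrum(c(300, 302, 304), c(10, 20, 10), "emission")
  expect_identical(intensity_at(s, 302), 20)
  expect_equal(intensity_at(s, 301), 15)   # midpoint of (300->10, 302->20)
  expect_error(intensity_at(s, 299), "outside grid")
  expect_error(intensity_at(s, 305), "outside grid")
  # monotone between adjacent grid points
  q <- seq(300, 302, 0.1)
  expect_true(all(diff(intensity_at(s, q)) >= 0))
})

test_that("dense- and coarse-grid queries agree within interpolation bound", {
  f <- function(w) exp(-(w - 340)^2 / 200)
  coarse <- spectrum(seq(300, 380, 4), f(seq(300, 380, 4)), "emission")
  fine <- spectrum(seq(300, 380, 0.25), f(seq(300, 380, 0.25)), "emission")
  q <- seq(301, 379, 0.7)
  # linear interpolation error bound: h^2/8 * max|f''|; f'' max ~ 1/100
  expect_lt(max(abs(intensity_at(coarse, q) - intensity_at(fine, q))),
            4^2 / 8 * 0.011)
})

test_that("titration series validates its mass-balance bookkeeping", {
  sp <- replicate(3, spectrum(300:310, rep(1, 11), "emission"),
                  simplify = FALSE)
  s <- titration_series(3e-6, c(0, 1e-6, 2e-6), 25, sp)
  expect_length(s, 3L)
  expect_error(titration_series(0, c(0, 1e-6, 2e-6), 25, sp), "positive")
  expect_error(titration_series(3e-6, c(0, 2e-6, 1e-6), 25, sp),
               "strictly increasing")
  expect_error(titration_series(3e-6, c(0, 1e-6), 25, sp),
               "number of spectra")
})

test_that("titration CSV round trip is lossless to numerical precision", {
  truth <- ground_truth(noise_sd = 0.01, seed = 11)
  s <- simulate_titration(truth)
  path <- withr::local_tempfile(fileext = ".csv")
  write_titration(s, path)
  s2 <- read_titration(path)
  expect_equal(s2$ligand_conc, s$ligand_conc, tolerance = 1e-12)
  expect_equal(s2$protein_conc, s$protein_conc)
  expect_equal(s2$temperature, s$temperature)
  for (i in seq_along(s$spectra)) {
    expect_equal(s2$spectra[[i]]$wavelength, s$spectra[[i]]$wavelength,
                 tolerance = 1e-12)
    expect_equal(s2$spectra[[i]]$value, s$spectra[[i]]$value,
                 tolerance = 1e-12)
  }
  expect_equal(s2$absorbance$A_ex, s$absorbance$A_ex, tolerance = 1e-12)
  expect_equal(s2$absorbance$A_em, s$absorbance$A_em, tolerance = 1e-12)
})

test_that("titration reader reports malformed files descriptively", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("series_id,kind,temperature_C,protein_conc_M,wavelength_nm,value",
               "a,emission,25,3e-6,300,1"), path)
  expect_error(read_titration(path), "ligand_conc_M")
  # duplicated wavelength inside one point -> invariant violation, named
  df <- data.frame(series_id = "a", kind = "emission", temperature_C = 25,
                   protein_conc_M = 3e-6, ligand_conc_M = 0,
                   wavelength_nm = c(300, 300, 301), value = c(1, 2, 3))
  write.csv(df, path, row.names = FALSE)
  expect_error(read_titration(path), "ligand_conc_M = 0")
  expect_error(read_titration("no/such/file.csv"), "not found")
})

test_that("write rejects non-finite values", {
  sp <- list(spectrum(300:310, rep(1, 11), "emission"),
             spectrum(300:310, c(rep(1, 10), NaN), "emission"))
  s <- titration_series(3e-6, c(0, 1e-6), 25, sp)
  path <- withr::local_tempfile(fileext = ".csv")
  expect_error(write_titration(s, path), "non-finite")
})

test_that("EEM and melt CSV round trips preserve values", {
  surf <- simulate_eem(seed = 3)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_eem(surf, p1)
  surf2 <- read_eem(p1)
  expect_equal(surf2$intensity, surf$intensity, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(surf2$excitation, surf$excitation)

  m <- simulate_melt(seed = 4)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_melt(m, p2)
  m2 <- read_melt(p2)
  expect_equal(m2$forward$mre, m$forward$mre, tolerance = 1e-12)
  expect_equal(m2$reverse$mre, m$reverse$mre, tolerance = 1e-12)
  expect_equal(m2$reverse$temperature, m$reverse$temperature)
})
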