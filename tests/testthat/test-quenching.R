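test_that("inner-filter correction evaluates the geometric-mean form", {
  expect_identical(inner_filter_correct(100, 0, 0), 100)
  expect_equal(inner_filter_correct(100, 1.0, 1.0), 1000)
  expect_equal(inner_filter_correct(250, 0.08, 0.04), 250 * 10^0.06)
  expect_error(inner_filter_correct(100, -0.1, 0), "non-negative")
  # multiplicative and order-independent across wavelengths
  f <- c(10, 20, 30); ae <- 0.05; am <- c(0.01, 0.02, 0.03)
  expect_equal(inner_filter_correct(f, ae, am)[c(3, 1, 2)],
               inner_filter_correct(f[c(3, 1, 2)], ae, am[c(3, 1, 2)]))
  expect_equal(inner_filter_correct(2 * f, ae, am),
               2 * inner_filter_correct(f, ae, am))
})

test_that("per-wavelength spectrum correction inverts simulated attenuation", {
  truth <- ground_truth(noise_sd = 0, seed = 1)
  s <- simulate_titration(truth)
  iv <- titration_intensities(s, correct = TRUE)
  iv0 <- titration_intensities(s, correct = FALSE)
  # corrected intensities must follow the clean quench model again
  theta <- equilibrium_1to1(truth$protein_conc, truth$ligand_conc,
                            truth$ka) / truth$protein_conc
  peak_w <- truth$band_center + truth$band_shift * theta
  expected <- truth$f0 * (1 - truth$quench_depth * theta) *
    exp(-(iv$ligand_conc * 0 + 336 - peak_w)^2 / (2 * truth$band_width^2))
  expect_equal(iv$f, expected, tolerance = 1e-9)
  expect_true(all(iv$f[-1] >= iv0$f[-1]))   # correction only raises
})

test_that("Stern-Volmer fit recovers a planted constant exactly", {
  q <- seq(0, 22.5e-6, 1.5e-6)
  ksv <- 8.60e4                       # 25 C constant
  f0 <- 1000
  f <- f0 / (1 + ksv * q)
  fit <- stern_volmer(q, f, tau0 = 6.38e-9)
  expect_equal(fit$ksv, ksv, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_identical(fit$retained, seq_along(q))
  expect_equal(fit$kq, ksv / 6.38e-9, tolerance = 1e-12)
  expect_equal(unname(coef(fit)), c(fit$ksv, fit$intercept))
})

test_that("constant intensity yields zero slope with a warning", {
  q <- seq(0, 10e-6, 2e-6)
  expect_warning(fit <- stern_volmer(q, rep(500, length(q))),
                 "no quenching")
  expect_equal(fit$ksv, 0)
  expect_equal(fit$intercept, 1)
})

test_that("linear-region selection excludes a planted curved tail", {
  q <- seq(0, 22.5e-6, 1.5e-6)
  ksv <- 8.60e4
  breakpoint <- 12e-6
  curv <- 6e9                       # upward curvature above 12 uM
  ratio <- 1 + ksv * q + curv * pmax(q - breakpoint, 0)^2
  idx <- select_linear_region(q, ratio)
  k_break <- max(which(q <= breakpoint))   # last clean point
  expect_true(abs(length(idx) - k_break) <= 1L)
  fit <- stern_volmer(q, ratio = ratio)
  expect_rel(fit$ksv, ksv, 0.02)
  expect_lt(length(fit$retained), length(q))
})

test_that("linear-region selection keeps clean data and minimal inputs", {
  q <- seq(0, 9e-6, 1.5e-6)
  expect_identical(select_linear_region(q, 1 + 5e4 * q), seq_along(q))
  q3 <- c(0, 1e-6, 2e-6)
  expect_identical(select_linear_region(q3, 1 + 5e4 * q3), 1:3)
  expect_error(select_linear_region(c(0, 1e-6), c(1, 1.1)), "at least 3")
})

test_that("noisy Stern-Volmer recovery stays within 2%", {
  set.seed(101)
  ksv <- 8.60e4
  q <- seq(0, 22.5e-6, length.out = 16)
  err <- replicate(200, {
    f0 <- 1000
    f <- f0 / (1 + ksv * q) * (1 + rnorm(16, sd = 0.01))
    fit <- suppressWarnings(stern_volmer(q, f, f0 = f0))
    abs(fit$ksv - ksv) / ksv
  })
  expect_lt(median(err), 0.02)
  expect_lt(mean(err), 0.02)
})

test_that("bimolecular quenching constant reproduces the tabulated bounds", {
  # K_SV extremes at 15 and 45 C with tau0 = 6.38 ns
  expect_rel(bimolecular_quenching(1.09e5, 6.38e-9), 1.71e13, 0.005)
  expect_rel(bimolecular_quenching(5.60e4, 6.38e-9), 0.88e13, 0.005)
  expect_identical(bimolecular_quenching(0, 6.38e-9), 0)
  expect_error(bimolecular_quenching(1e5, 0), "positive")
  # linear in K_SV, inverse in tau0
  expect_equal(bimolecular_quenching(2e5, 6.38e-9),
               2 * bimolecular_quenching(1e5, 6.38e-9))
  expect_equal(bimolecular_quenching(1e5, 2 * 6.38e-9),
               bimolecular_quenching(1e5, 6.38e-9) / 2)
})

test_that("temperature trend of K_SV classifies the quenching mechanism", {
  ksv <- c(1.09e5, 8.60e4, 7.15e4, 5.60e4)   # decreasing with T
  cls <- classify_quenching(ksv, temperature = c(15, 25, 35, 45),
                            tau0 = 6.38e-9)
  expect_identical(cls$label, "static")
  expect_true(cls$above_diffusion_limit)
  cls2 <- classify_quenching(rev(ksv), temperature = c(15, 25, 35, 45))
  expect_identical(cls2$label, "dynamic")
  cls3 <- classify_quenching(c(1e5, 2e5, 1.5e5),
                             temperature = c(15, 25, 35))
  expect_identical(cls3$label, "ambiguous")
  expect_error(classify_quenching(1e5, temperature = 25), ">= 2")
})
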