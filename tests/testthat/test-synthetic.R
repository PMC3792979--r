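test_that("1:1 equilibrium matches a bisection oracle across K_a", {
  p <- 3e-6
  for (ka in 10^seq(3, 9, by = 1)) {
    for (d in c(0.5e-6, 3e-6, 22.5e-6)) {
      pd <- equilibrium_1to1(p, d, ka)
      pd_oracle <- bisect_equilibrium(p, d, ka)
      expect_lt(abs(pd - pd_oracle) / min(p, d), 1e-12)
      # mass-balance residual, relative form
      expect_lt(abs(ka * (p - pd) * (d - pd) - pd) / (1 + ka * p * d),
                1e-10 * (1 + pd / min(p, d)))
    }
  }
})

test_that("1:1 equilibrium limits are exact", {
  expect_identical(equilibrium_1to1(3e-6, 0, 1e5), 0)
  # K -> infinity: everything binds up to the limiting species
  expect_equal(equilibrium_1to1(3e-6, 1.5e-6, 1e15), 1.5e-6,
               tolerance = 1e-9)
  expect_equal(equilibrium_1to1(3e-6, 22.5e-6, 1e15), 3e-6,
               tolerance = 1e-9)
  expect_error(equilibrium_1to1(-1e-6, 1e-6, 1e5), "non-negative")
  expect_error(equilibrium_1to1(3e-6, 1e-6, 0), "positive")
})

test_that("simulators are bit-identical under a fixed seed", {
  a <- simulate_titration(ground_truth(seed = 77))
  b <- simulate_titration(ground_truth(seed = 77))
  expect_identical(a, b)
  expect_false(identical(
    a, simulate_titration(ground_truth(seed = 78))))
  expect_identical(simulate_melt(seed = 5), simulate_melt(seed = 5))
  expect_identical(simulate_eem(noise_sd = 0.01, seed = 6),
                   simulate_eem(noise_sd = 0.01, seed = 6))
})

test_that("zero quench depth gives a flat intensity series", {
  s <- simulate_titration(ground_truth(quench_depth = 0, noise_sd = 0,
                                       eps_ex = 0, eps_em = 0,
                                       band_shift = 0))
  iv <- titration_intensities(s, correct = FALSE)
  expect_equal(iv$f, rep(iv$f[1], length(iv$f)), tolerance = 1e-12)
})

test_that("simulated titration analyzed end-to-end recovers K_a", {
  truth <- ground_truth(noise_sd = 0, eps_ex = 0, eps_em = 0,
                        quench_depth = 0.999, band_shift = 0)
  fit <- binding_isotherm(simulate_titration(truth))
  expect_rel(fit$ka, truth$ka, 0.01)
})

test_that("multi-temperature generator follows the van't Hoff relation", {
  truth <- ground_truth(noise_sd = 0, quench_depth = 0.999, seed = 31)
  series <- simulate_multitemp(truth, delta_H = -15.48, delta_S = 44.06)
  expect_named(series, c("15", "25", "35", "45"))
  fits <- lapply(series, binding_isotherm)
  ka <- vapply(fits, `[[`, numeric(1L), "ka")
  # affinity falls with temperature for exothermic binding
  expect_true(all(diff(ka) < 0))
  vh <- vant_hoff(ka, c(15, 25, 35, 45), unit = "C")
  expect_rel(vh$delta_H, -15.48, 0.02)
  expect_rel(vh$delta_S, 44.06, 0.02)
  # dH = 0 -> identical K at all temperatures
  iso <- simulate_multitemp(truth, delta_H = 0, delta_S = 44.06)
  ka_iso <- vapply(lapply(iso, binding_isotherm), `[[`, numeric(1L), "ka")
  expect_lt(diff(range(ka_iso)) / mean(ka_iso), 1e-6)
})

test_that("melt generator honours its reversibility parameter", {
  m <- simulate_melt(reversibility = 1, noise_sd = 0)
  expect_equal(melt_analysis(m$forward, m$reverse)$recovery_percent, 100,
               tolerance = 1e-9)
  m0 <- simulate_melt(reversibility = 0.55, noise_sd = 0)
  expect_equal(melt_analysis(m0$forward, m0$reverse)$recovery_percent, 55,
               tolerance = 1e-9)
})

test_that("competitive solver matches the grid-search oracle", {
  cases <- list(
    list(p = 10e-6, m = 10e-6, c = 40e-6, km = 1e5, kc = 2e5),
    list(p = 3e-6, m = 3e-6, c = 24e-6, km = 3e5, kc = 1e5),
    list(p = 10e-6, m = 20e-6, c = 80e-6, km = 1e6, kc = 1e6))
  for (cs in cases) {
    got <- competitive_equilibrium(cs$p, cs$m, cs$c, cs$km, cs$kc)
    oracle <- grid_competitive(cs$p, cs$m, cs$c, cs$km, cs$kc)
    expect_lt(abs(got$m_free - oracle$m_free) / oracle$m_free, 1e-8)
    expect_lt(abs(got$c_free - oracle$c_free) / oracle$c_free, 1e-8)
    expect_lt(abs(got$p_free - oracle$p_free) / oracle$p_free, 1e-8)
  }
})

test_that("competition lowers the marker-bound fraction", {
  alone <- competitive_equilibrium(10e-6, 10e-6, 0, 1e5, 1e5)
  with_c <- competitive_equilibrium(10e-6, 10e-6, 10e-6, 1e5, 1e5)
  expect_lt(with_c$marker_bound_fraction, alone$marker_bound_fraction)
  # no competitor: reduces to the 1:1 equilibrium
  expect_equal(alone$pm, equilibrium_1to1(10e-6, 10e-6, 1e5),
               tolerance = 1e-9)
})

test_that("model-mismatch quench mode still gives a usable titration", {
  s <- simulate_titration(ground_truth(quench_mode = "bound_ligand",
                                       n_sites = 2, noise_sd = 0,
                                       quench_depth = 0.7))
  iv <- titration_intensities(s)
  expect_true(all(diff(iv$f) < 0))
  fit <- suppressWarnings(binding_isotherm(s))
  expect_gt(fit$ka, 0)
})
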