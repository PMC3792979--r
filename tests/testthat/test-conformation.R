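make_sync_series <- function(centers, grid = seq(310, 370, 1),
                             delta_lambda = 60) {
  lapply(centers, function(c0)
    spectrum(grid, exp(-(grid - c0)^2 / (2 * 8^2)), "synchronous",
             meta = list(delta_lambda = delta_lambda)))
}

test_that("synchronous shift detects a planted blue shift", {
  # Trp channel: center translated -5 nm across the titration
  centers <- seq(340, 335, length.out = 11)
  sh <- synchronous_shift(make_sync_series(centers), delta_lambda = 60)
  expect_equal(sh$net_shift, -5, tolerance = 0.1)
  # Tyr channel: fixed center -> no shift
  sh15 <- synchronous_shift(make_sync_series(rep(298, 11),
                                             grid = seq(280, 320, 1),
                                             delta_lambda = 15))
  expect_equal(sh15$net_shift, 0, tolerance = 1e-9)
  # identical spectra -> zero shift
  s <- make_sync_series(c(340, 340, 340))
  expect_identical(synchronous_shift(s)$net_shift, 0)
})

test_that("synchronous shift rejects flat or inconsistent input", {
  flat <- spectrum(300:320, rep(1, 21), "synchronous")
  expect_error(synchronous_shift(list(flat)), "flat")
  mixed <- c(make_sync_series(340, delta_lambda = 15),
             make_sync_series(340, delta_lambda = 60))
  expect_error(synchronous_shift(mixed), "inconsistent")
})

test_that("parabolic refinement beats the grid resolution", {
  grid <- seq(300, 380, 2)                  # coarse 2 nm grid
  s <- list(spectrum(grid, exp(-(grid - 336.7)^2 / (2 * 12^2)),
                     "synchronous"))
  sh <- synchronous_shift(s)
  expect_lt(abs(sh$peaks$peak_nm[1] - 336.7), 0.1)
  expect_equal(sh$peaks$discrete_peak_nm[1], 336)
})

test_that("EEM peak finder recovers planted peaks and labels scatter", {
  surf <- simulate_eem(seed = 9)
  pk <- find_3d_peaks(surf, scatter_tol = 5)
  p1 <- pk[pk$label == "peak1", ]
  p2 <- pk[pk$label == "peak2", ]
  expect_equal(nrow(p1), 1L)
  expect_equal(nrow(p2), 1L)
  expect_lte(abs(p1$excitation - 280), 5)   # +- 1 grid step
  expect_lte(abs(p1$emission - 335), 5)
  expect_lte(abs(p2$excitation - 235), 5)
  expect_lte(abs(p2$emission - 330), 5)
  expect_true(any(pk$label == "rayleigh_a"))
  # flat surface: no peaks at all
  flat <- eem_surface(seq(220, 350, 10), seq(220, 500, 10),
                      matrix(1, 14, 29))
  expect_identical(nrow(find_3d_peaks(flat)), 0L)
  # single off-diagonal spike
  m <- matrix(0, 14, 29)
  m[7, 12] <- 10
  one <- find_3d_peaks(eem_surface(seq(220, 350, 10), seq(220, 500, 10), m))
  expect_identical(nrow(one), 1L)
  expect_identical(one$label, "peak1")
})

test_that("scatter labels are mutually exclusive away from the origin", {
  # a maximum with excitation > 2 * tol cannot satisfy both ridge rules
  surf <- simulate_eem(seed = 10)
  pk <- find_3d_peaks(surf, scatter_tol = 5)
  on_both <- abs(pk$emission - pk$excitation) <= 5 &
    abs(pk$emission - 2 * pk$excitation) <= 5 & pk$excitation > 10
  expect_false(any(on_both))
})

test_that("peak trajectories reproduce a planted intensity decline", {
  ints <- c(683, 581, 448, 390)             # Trp/Tyr peak fading
  ems <- c(335, 332, 330, 329)              # with a blue shift
  surfaces <- lapply(seq_along(ints), function(i)
    simulate_eem(peaks = data.frame(excitation = c(280, 235),
                                    emission = c(ems[i], 330),
                                    intensity = c(ints[i], 300),
                                    width_ex = c(15, 8),
                                    width_em = c(15, 12))))
  tr <- peak_trajectory(surfaces)
  expect_true("peak1" %in% names(tr))
  p1 <- tr[["peak1"]]
  expect_false(any(p1$missing))
  expect_true(all(diff(p1$intensity) < 0))
  expect_equal(order(p1$intensity, decreasing = TRUE), 1:4)
  # recovered intensities close to planted apex values
  expect_equal(p1$intensity, ints, tolerance = 0.1)
  expect_true(all(diff(p1$emission) <= 0))
  # identical surfaces -> constant trajectory
  tr2 <- peak_trajectory(list(surfaces[[1]], surfaces[[1]]))
  expect_equal(tr2[["peak1"]]$intensity[1], tr2[["peak1"]]$intensity[2])
  # a missing peak is flagged
  gone <- simulate_eem(peaks = data.frame(excitation = 280, emission = 335,
                                          intensity = 600, width_ex = 15,
                                          width_em = 15))
  tr3 <- peak_trajectory(list(surfaces[[1]], gone))
  expect_true(tr3[["peak2"]]$missing[2])
})

test_that("mean residue ellipticity conversion is linear and scaled", {
  expect_identical(mre_convert(0, 0.1, 3e-6), 0)
  expect_equal(mre_convert(-30, 0.1, 3e-6, 585),
               -30 / (10 * 585 * 3e-6 * 0.1))
  expect_equal(mre_convert(-30, 0.1, 3e-6, 585), -17094, tolerance = 0.5)
  expect_equal(mre_convert(-60, 0.1, 3e-6), 2 * mre_convert(-30, 0.1, 3e-6))
  expect_equal(mre_convert(-30, 0.2, 3e-6), mre_convert(-30, 0.1, 3e-6) / 2)
  expect_equal(mre_convert(-30, 0.1, 6e-6), mre_convert(-30, 0.1, 3e-6) / 2)
  expect_error(mre_convert(-30, 0, 3e-6), "positive")
})

test_that("melt analysis recovers reversibility and onset", {
  m <- simulate_melt(reversibility = 0.87, seed = 21)
  ma <- melt_analysis(m$forward, m$reverse)
  expect_equal(ma$recovery_percent, 87, tolerance = 1)
  expect_true(ma$onset_T >= 45 && ma$onset_T <= 50)
  m2 <- simulate_melt(reversibility = 0.55, seed = 22)
  expect_equal(melt_analysis(m2$forward, m2$reverse)$recovery_percent,
               55, tolerance = 1)
  # identical scans -> full recovery
  f <- simulate_melt(noise_sd = 0, seed = 23)$forward
  r <- melt_curve(rev(f$temperature), rev(f$mre), "reverse")
  expect_equal(melt_analysis(f, r)$recovery_percent, 100,
               tolerance = 1e-9)
})

test_that("melt recovery is scale invariant and flags flat curves", {
  m <- simulate_melt(reversibility = 0.7, seed = 24)
  scaled <- list(
    forward = melt_curve(m$forward$temperature, 3.7 * m$forward$mre,
                         "forward"),
    reverse = melt_curve(m$reverse$temperature, 3.7 * m$reverse$mre,
                         "reverse"))
  expect_equal(melt_analysis(m$forward, m$reverse)$recovery_percent,
               melt_analysis(scaled$forward, scaled$reverse)$recovery_percent,
               tolerance = 1e-9)
  flat <- melt_curve(seq(25, 80, 1), rep(-21000, 56), "forward")
  flat_r <- melt_curve(seq(80, 25, -1), rep(-21000, 56), "reverse")
  expect_warning(ma <- melt_analysis(flat, flat_r), "no unfolding")
  expect_true(ma$no_transition)
  expect_true(is.na(ma$onset_T))
})
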