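# Independent oracles used across tests. These deliberately solve the
# same problems as the package by different routes (bisection, grid
# search, closed forms) so that agreement is evidence, not tautology.

# 1:1 equilibrium by bisection on the mass-balance residual
# K*(P - PD)*(D - PD) - PD = 0, PD in [0, min(P, D)]
bisect_equilibrium <- function(p_total, d_total, ka, iter = 200L) {
  if (d_total == 0 || p_total == 0) return(0)
  resid <- function(pd) ka * (p_total - pd) * (d_total - pd) - pd
  lo <- 0; hi <- min(p_total, d_total)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (resid(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# competitive three-species equilibrium by refining 2-D grid search
# over (m_free, c_free); protein balance closes the system.
grid_competitive <- function(p_total, m_total, c_total, k_m, k_c,
                             n_grid = 21L, refinements = 40L) {
  obj <- function(mf, cf) {
    pf <- p_total / (1 + k_m * mf + k_c * cf)
    r1 <- mf * (1 + k_m * pf) - m_total
    r2 <- cf * (1 + k_c * pf) - c_total
    r1^2 + r2^2
  }
  m_lo <- 0; m_hi <- m_total
  c_lo <- 0; c_hi <- c_total
  for (r in seq_len(refinements)) {
    ms <- seq(m_lo, m_hi, length.out = n_grid)
    cs <- seq(c_lo, c_hi, length.out = n_grid)
    vals <- outer(ms, cs, Vectorize(obj))
    idx <- which(vals == min(vals), arr.ind = TRUE)[1L, ]
    mw <- (m_hi - m_lo) / (n_grid - 1L)
    cw <- (c_hi - c_lo) / (n_grid - 1L)
    m_lo <- max(0, ms[idx[1L]] - mw); m_hi <- min(m_total, ms[idx[1L]] + mw)
    c_lo <- max(0, cs[idx[2L]] - cw); c_hi <- min(c_total, cs[idx[2L]] + cw)
  }
  mf <- (m_lo + m_hi) / 2; cf <- (c_lo + c_hi) / 2
  pf <- p_total / (1 + k_m * mf + k_c * cf)
  list(p_free = pf, m_free = mf, c_free = cf)
}

# exact-equilibrium quench titration: full quench depth so that the
# fractional quench equals the fractional saturation exactly
exact_quench_titration <- function(ka, p_total = 3e-6,
                                   d_total = seq(0, 22.5e-6, 1.5e-6),
                                   f0 = 1000, noise_sd = 0) {
  theta <- equilibrium_1to1(p_total, d_total, ka) / p_total
  f <- f0 * (1 - theta)
  if (noise_sd > 0) f <- f * (1 + stats::rnorm(length(f), sd = noise_sd))
  list(d_total = d_total, f = f, f0 = f0, p_total = p_total)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
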