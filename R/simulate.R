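# Synthetic-data generators with known ground truth. Every input the
# analysis pipeline consumes can be produced here, so all stages are
# testable end to end without instrument data. Defaults mirror a
# serum-albumin quench titration design: 3 uM protein, 0-22.5 uM ligand
# in 1.5 uM steps, excitation 280 nm, emission band near 336 nm, four
# temperatures 15/25/35/45 C.

#' Ground truth for a synthetic quench titration
#'
#' Bundles the generative parameters of [simulate_titration()]. The
#' defaults emulate the albumin study design: 1:1 binding with
#' K_a = 1.03e5 M^-1 at 25 C, 72 percent maximal quench and a 14 nm
#' blue shift at saturation, and a ligand that absorbs at both the
#' excitation and emission wavelengths (inner-filter artifact).
#'
#' @param ka association constant, M^-1.
#' @param n_sites binding sites per protein (1 for 1:1 binding; values
#'   > 1 scale the bound-ligand count in the model-mismatch mode).
#' @param protein_conc total protein, mol/L.
#' @param ligand_conc total-ligand grid, mol/L, ascending from 0.
#' @param temperature degrees Celsius.
#' @param quench_depth maximal fractional quench at full occupancy, in
#'   `[0, 1)`. The double-log estimator assumes complete quenching of
#'   the fluorophore in the complex (depth 1); the default 0.72 mirrors
#'   the observed 72 percent intensity loss and exercises that
#'   model-mismatch.
#' @param band_center emission-band center of the ligand-free protein,
#'   nm.
#' @param band_shift band-center shift at full occupancy, nm (negative
#'   = blue shift).
#' @param band_width Gaussian band standard deviation, nm.
#' @param f0 peak intensity of the ligand-free spectrum, a.u.
#' @param eps_ex,eps_em ligand molar extinction coefficients
#'   (M^-1 cm^-1) at the excitation and emission wavelengths, driving
#'   the simulated inner-filter attenuation (A = eps x ligand conc for
#'   a 1 cm path).
#' @param noise_sd relative (multiplicative Gaussian) noise standard
#'   deviation.
#' @param wavelength emission wavelength grid, nm.
#' @param quench_mode `"occupancy"` ties the fractional quench linearly
#'   to fractional saturation (the estimator's own assumption);
#'   `"bound_ligand"` ties it to the bound-ligand count divided by
#'   `n_sites x protein` (differs when `n_sites > 1`), for robustness
#'   tests.
#' @param seed integer seed; fixed seeds give bit-identical output.
#' @return A list of class `"ground_truth"`.
#' @export
ground_truth <- function(ka = 1.03e5, n_sites = 1, protein_conc = 3e-6,
                         ligand_conc = seq(0, 22.5e-6, by = 1.5e-6),
                         temperature = 25, quench_depth = 0.72,
                         band_center = 336, band_shift = -14,
                         band_width = 20, f0 = 1000,
                         eps_ex = 4000, eps_em = 1000,
                         noise_sd = 0.01,
                         wavelength = seq(300, 380, by = 1),
                         quench_mode = c("occupancy", "bound_ligand"),
                         seed = NULL) {
  quench_mode <- match.arg(quench_mode)
  stopifnot(ka > 0, protein_conc > 0, all(ligand_conc >= 0),
            quench_depth >= 0, quench_depth < 1, noise_sd >= 0,
            eps_ex >= 0, eps_em >= 0)
  structure(as.list(environment()), class = "ground_truth")
}

#' Exact 1:1 binding equilibrium
#'
#' Bound-complex concentration for total protein `p_total`, total
#' ligand `d_total` and association constant `ka`, from the quadratic
#' mass balance
#' \deqn{K_a ([P_T]-[PD]) ([D_T]-[PD]) = [PD]}
#' solved in a numerically stabilized form (no catastrophic
#' cancellation for large `ka`). Vectorized over `d_total`.
#'
#' @param p_total total protein, mol/L (>= 0).
#' @param d_total total ligand, mol/L (>= 0, vectorized).
#' @param ka association constant, M^-1 (> 0).
#' @return Bound concentration `[PD]` in mol/L.
#' @export
equilibrium_1to1 <- function(p_total, d_total, ka) {
  if (any(p_total < 0) || any(d_total < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  if (ka <= 0) stop("ka must be positive", call. = FALSE)
  # solve for free ligand: ka*Df^2 + (1 + ka*(P - D))*Df - D = 0,
  # picking the stable root branch
  beta <- 1 + ka * (p_total - d_total)
  disc <- sqrt(beta^2 + 4 * ka * d_total)
  d_free <- ifelse(beta >= 0,
                   2 * d_total / (beta + disc),
                   (disc - beta) / (2 * ka))
  pmax(d_total - d_free, 0)
}

#' Simulate a fluorescence quench titration
#'
#' For each total-ligand point the exact 1:1 equilibrium gives the
#' occupancy \eqn{\theta = [PD]/[P_T]}; the emission spectrum is a
#' Gaussian band with peak intensity \eqn{F_0 (1 - q\theta)} (quench
#' depth `q`) and center `band_center + band_shift * theta`. The
#' observed spectrum is attenuated by the inner-filter factor
#' \eqn{10^{-(A_{ex}+A_{em})/2}} with \eqn{A = \varepsilon [D_T]}, and
#' the absorbance increments are recorded in the series so the analysis
#' can invert the attenuation exactly. Multiplicative Gaussian noise is
#' applied last.
#'
#' @param truth a [ground_truth()] object.
#' @return A [titration_series()].
#' @examples
#' s <- simulate_titration(ground_truth(noise_sd = 0, seed = 1))
#' stern_volmer(titration_intensities(s)$ligand_conc,
#'              titration_intensities(s)$f)
#' @export
simulate_titration <- function(truth = ground_truth()) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!is.null(truth$seed)) set.seed(truth$seed)
  pd <- equilibrium_1to1(truth$protein_conc, truth$ligand_conc, truth$ka)
  theta <- pd / truth$protein_conc
  qfrac <- switch(truth$quench_mode,
                  occupancy = theta,
                  bound_ligand = pmin(truth$n_sites * pd /
                    (truth$n_sites * truth$protein_conc), 1))
  a_ex <- truth$eps_ex * truth$ligand_conc
  a_em <- truth$eps_em * truth$ligand_conc
  spectra <- vector("list", length(truth$ligand_conc))
  for (i in seq_along(truth$ligand_conc)) {
    center <- truth$band_center + truth$band_shift * theta[i]
    peak <- truth$f0 * (1 - truth$quench_depth * qfrac[i])
    v <- peak * exp(-(truth$wavelength - center)^2 /
                      (2 * truth$band_width^2))
    v <- v * 10^(-(a_ex[i] + a_em[i]) / 2)
    if (truth$noise_sd > 0)
      v <- v * (1 + stats::rnorm(length(v), sd = truth$noise_sd))
    v <- pmax(v, 0)
    spectra[[i]] <- spectrum(truth$wavelength, v, kind = "emission",
                             meta = list(excitation_nm = 280,
                                         temperature_C = truth$temperature))
  }
  titration_series(protein_conc = truth$protein_conc,
                   ligand_conc = truth$ligand_conc,
                   temperature = truth$temperature,
                   spectra = spectra,
                   absorbance = data.frame(A_ex = a_ex, A_em = a_em))
}

#' Simulate titrations at several temperatures
#'
#' The association constant at each temperature follows the van't Hoff
#' relation \eqn{K_a(T) = \exp(-\Delta H/(R T) + \Delta S/R)}; one
#' titration is generated per temperature.
#'
#' @param truth a [ground_truth()] template (its `ka` and `temperature`
#'   are overridden per temperature).
#' @param delta_H enthalpy change, kJ mol^-1.
#' @param delta_S entropy change, J mol^-1 K^-1.
#' @param temperatures degrees Celsius.
#' @param kelvin_offset see [celsius_to_kelvin()].
#' @return Named list of [titration_series()], names = temperature.
#' @export
simulate_multitemp <- function(truth = ground_truth(),
                               delta_H = -15.48, delta_S = 44.06,
                               temperatures = c(15, 25, 35, 45),
                               kelvin_offset = 273.15) {
  t_k <- celsius_to_kelvin(temperatures, kelvin_offset)
  ka <- exp(-delta_H * 1000 / (GAS_CONSTANT * t_k) +
              delta_S / GAS_CONSTANT)
  out <- vector("list", length(temperatures))
  for (i in seq_along(temperatures)) {
    tr <- truth
    tr$ka <- ka[i]
    tr$temperature <- temperatures[i]
    if (!is.null(truth$seed)) tr$seed <- truth$seed + i
    out[[i]] <- simulate_titration(tr)
  }
  names(out) <- format(temperatures)
  out
}

#' Simulate a two-state thermal melt with partial reversibility
#'
#' Forward (heating) scan: two-state sigmoid between a native and a
#' denatured baseline,
#' \eqn{s(T) = s_{den} + (s_{nat} - s_{den}) / (1 + e^{(T - T_m)/w})}.
#' Reverse (cooling) scan:
#' `baseline + reversibility * (forward - baseline)` evaluated on the
#' cooling grid, i.e. only a fraction `reversibility` of the unfolded
#' protein refolds. The denatured baseline defaults to 0 (random-coil
#' ellipticity at 222 nm is near zero), which makes the reverse-scan
#' start signal equal `reversibility` times the native signal.
#'
#' @param tm midpoint temperature, degrees C.
#' @param cooperativity transition width `w` in degrees C (smaller =
#'   steeper).
#' @param baselines length-2 vector `c(native, denatured)` MRE at
#'   222 nm (deg cm^2 dmol^-1).
#' @param reversibility fraction of the signal regained on cooling, in
#'   `[0, 1]`.
#' @param temperature forward-scan temperature grid, degrees C.
#' @param noise_sd relative noise (of the native signal magnitude).
#' @param seed integer seed.
#' @return List with `forward` and `reverse` [melt_curve()]s.
#' @export
simulate_melt <- function(tm = 66, cooperativity = 4,
                          baselines = c(native = -21000, denatured = 0),
                          reversibility = 0.87,
                          temperature = seq(25, 80, by = 1),
                          noise_sd = 0.002, seed = NULL) {
  stopifnot(reversibility >= 0, reversibility <= 1)
  if (!is.null(seed)) set.seed(seed)
  s_nat <- baselines[[1L]]; s_den <- baselines[[2L]]
  shape <- function(tt) s_den + (s_nat - s_den) /
    (1 + exp((tt - tm) / cooperativity))
  noise <- function(n) stats::rnorm(n, sd = noise_sd * abs(s_nat))
  fwd <- shape(temperature) + noise(length(temperature))
  rev_grid <- rev(temperature)
  rv <- s_den + reversibility * (shape(rev_grid) - s_den) +
    noise(length(rev_grid))
  list(forward = melt_curve(temperature, fwd, "forward"),
       reverse = melt_curve(rev_grid, rv, "reverse"))
}

#' Simulate an excitation-emission matrix
#'
#' Sum of 2-D Gaussian fluorophore peaks plus Rayleigh
#' (emission = excitation) and second-order (emission = 2 x excitation)
#' scatter ridges. Default peaks mirror the native-albumin EEM: the
#' Trp/Tyr peak at excitation 280 / emission 335 nm and the backbone
#' peak at 235/330 nm.
#'
#' @param peaks data frame with columns `excitation`, `emission`,
#'   `intensity`, `width_ex`, `width_em` (Gaussian SDs, nm).
#' @param scatter named vector `c(rayleigh = , second = )` of ridge
#'   amplitudes at 300 nm excitation; the amplitude along each ridge
#'   falls off as `(excitation/300)^-4` (Rayleigh wavelength
#'   dependence), and the ridge cross-section SD is 3 nm.
#' @param excitation,emission wavelength grids, nm.
#' @param noise_sd relative noise on the surface.
#' @param seed integer seed.
#' @return An [eem_surface()].
#' @export
simulate_eem <- function(peaks = data.frame(
                           excitation = c(280, 235),
                           emission = c(335, 330),
                           intensity = c(683, 359),
                           width_ex = c(15, 8),
                           width_em = c(15, 12)),
                         scatter = c(rayleigh = 100, second = 150),
                         excitation = seq(220, 350, by = 5),
                         emission = seq(220, 500, by = 5),
                         noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0, length(excitation), length(emission))
  em_row <- matrix(emission, length(excitation), length(emission),
                   byrow = TRUE)
  ex_col <- matrix(excitation, length(excitation), length(emission))
  if (!is.null(peaks) && nrow(peaks))
    for (k in seq_len(nrow(peaks)))
      m <- m + peaks$intensity[k] *
        exp(-(ex_col - peaks$excitation[k])^2 /
              (2 * peaks$width_ex[k]^2) -
            (em_row - peaks$emission[k])^2 /
              (2 * peaks$width_em[k]^2))
  ridge_sd <- 3
  lam4 <- (ex_col / 300)^-4          # Rayleigh wavelength dependence
  m <- m + scatter[["rayleigh"]] * lam4 *
    exp(-(em_row - ex_col)^2 / (2 * ridge_sd^2))
  m <- m + scatter[["second"]] * lam4 *
    exp(-(em_row - 2 * ex_col)^2 / (2 * ridge_sd^2))
  if (noise_sd > 0)
    m <- m * (1 + matrix(stats::rnorm(length(m), sd = noise_sd),
                         nrow(m), ncol(m)))
  eem_surface(excitation, emission, m)
}

#' Three-species competitive binding equilibrium
#'
#' Protein P binding two ligands (marker M, competitor C) mutually
#' exclusively at one site: \eqn{P + M \rightleftharpoons PM},
#' \eqn{P + C \rightleftharpoons PC}. Solved by damped fixed-point
#' iteration on the free-protein concentration until every mass-balance
#' residual falls below `tol` (relative).
#'
#' @param p_total,m_total,c_total total concentrations, mol/L.
#' @param k_m,k_c association constants, M^-1.
#' @param tol relative residual tolerance (default 1e-12).
#' @param max_iter iteration cap.
#' @param damping step fraction in `(0, 1]`.
#' @return List with `p_free`, `m_free`, `c_free`, `pm`, `pc`,
#'   `marker_bound_fraction` (= pm / m_total) and `iterations`.
#' @export
competitive_equilibrium <- function(p_total, m_total, c_total, k_m, k_c,
                                    tol = 1e-12, max_iter = 100000L,
                                    damping = 0.5) {
  stopifnot(p_total >= 0, m_total >= 0, c_total >= 0, k_m > 0, k_c > 0)
  pf <- p_total
  scale <- max(p_total, m_total, c_total, .Machine$double.xmin)
  for (it in seq_len(max_iter)) {
    mf <- m_total / (1 + k_m * pf)
    cf <- c_total / (1 + k_c * pf)
    pf_new <- p_total / (1 + k_m * mf + k_c * cf)
    pf <- pf + damping * (pf_new - pf)
    mf <- m_total / (1 + k_m * pf)
    cf <- c_total / (1 + k_c * pf)
    res <- max(abs(pf * (1 + k_m * mf + k_c * cf) - p_total),
               abs(mf * (1 + k_m * pf) - m_total),
               abs(cf * (1 + k_c * pf) - c_total)) / scale
    if (res < tol) break
  }
  if (res >= tol)
    warning(sprintf("competitive equilibrium: residual %g after %d iterations",
                    res, max_iter))
  list(p_free = pf, m_free = mf, c_free = cf,
       pm = k_m * pf * mf, pc = k_c * pf * cf,
       marker_bound_fraction = if (m_total > 0) k_m * pf * mf / m_total
                               else NA_real_,
       iterations = it)
}

#' Simulate a site-marker displacement titration
#'
#' When the competitor shares the marker's site (`shared_site = TRUE`)
#' the three-species competitive equilibrium is solved at each
#' competitor/protein ratio and the signal is proportional to the
#' marker-bound fraction; otherwise marker binding is unaffected and
#' the signal stays flat (apart from an optional additive baseline term
#' from the competitor-protein complex and noise).
#'
#' @param k_marker,k_competitor association constants, M^-1.
#' @param p_total total protein, mol/L.
#' @param marker_total total marker, mol/L.
#' @param ratio competitor/protein molar-ratio grid, ascending from 0.
#' @param shared_site logical.
#' @param marker,site passed to [displacement_series()].
#' @param signal_scale signal value corresponding to a fully bound
#'   marker.
#' @param baseline_amplitude additive signal per unit molar ratio from
#'   the competitor-protein complex (confounder; default 0).
#' @param noise_sd relative noise.
#' @param seed integer seed.
#' @return A [displacement_series()].
#' @export
simulate_displacement <- function(k_marker = 1e5, k_competitor = 1e5,
                                  p_total = 10e-6,
                                  marker_total = 10e-6,
                                  ratio = 0:8, shared_site = TRUE,
                                  marker = "marker", site = "I",
                                  signal_scale = 100,
                                  baseline_amplitude = 0,
                                  noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bound <- vapply(ratio, function(rr) {
    if (shared_site)
      competitive_equilibrium(p_total, marker_total, rr * p_total,
                              k_marker, k_competitor)$marker_bound_fraction
    else
      equilibrium_1to1(p_total, marker_total, k_marker) / marker_total
  }, numeric(1L))
  sig <- signal_scale * bound + baseline_amplitude * ratio
  if (noise_sd > 0)
    sig <- sig * (1 + stats::rnorm(length(sig), sd = noise_sd))
  displacement_series(marker = marker, site = site, ratio = ratio,
                      signal = sig)
}
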