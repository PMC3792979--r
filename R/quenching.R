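#' Inner-filter correction of fluorescence intensities
#'
#' Corrects measured fluorescence for attenuation of the excitation beam
#' and re-absorption of emitted light by the added ligand, using the
#' geometric-mean absorbance correction
#' \deqn{F_{cor} = F_{obs} \cdot 10^{(A_{ex} + A_{em})/2}}
#' where \eqn{A_{ex}} and \eqn{A_{em}} are the absorbance increments at
#' the excitation and emission wavelengths. All arguments are vectorized.
#'
#' @param f_obs observed (measured) fluorescence intensity.
#' @param a_ex absorbance increment at the excitation wavelength
#'   (dimensionless, >= 0).
#' @param a_em absorbance increment at the emission wavelength (>= 0).
#' @return Corrected fluorescence intensity.
#' @examples
#' inner_filter_correct(100, 0, 0)      # 100
#' inner_filter_correct(100, 1, 1)      # 1000
#' @export
inner_filter_correct <- function(f_obs, a_ex, a_em) {
  if (any(a_ex < 0, na.rm = TRUE) || any(a_em < 0, na.rm = TRUE))
    stop("absorbance increments must be non-negative", call. = FALSE)
  f_obs * 10^((a_ex + a_em) / 2)
}

#' Inner-filter correction of a full emission spectrum
#'
#' Per-wavelength variant: the emission-side absorbance is evaluated at
#' each emission wavelength by interpolating an absorbance spectrum.
#'
#' @param emission an emission [spectrum()].
#' @param a_ex absorbance increment at the excitation wavelength (scalar).
#' @param absorbance an absorbance [spectrum()] covering the emission
#'   wavelength range.
#' @return A corrected emission [spectrum()].
#' @export
inner_filter_correct_spectrum <- function(emission, a_ex, absorbance) {
  stopifnot(inherits(emission, "spectrum"), inherits(absorbance, "spectrum"))
  a_em <- intensity_at(absorbance, emission$wavelength)
  spectrum(emission$wavelength,
           inner_filter_correct(emission$value, a_ex, a_em),
           kind = emission$kind, meta = emission$meta)
}

#' Reference-wavelength intensities of a titration series
#'
#' Extracts F at a reference wavelength from every spectrum of a
#' titration, optionally applying the inner-filter correction from the
#' stored per-point absorbance increments.
#'
#' @param series a [titration_series()].
#' @param wavelength reference wavelength (nm); default is the emission
#'   maximum of the ligand-free (first) spectrum.
#' @param correct apply the inner-filter correction using the series'
#'   absorbance increments (default `TRUE` when increments are present).
#' @return A data frame with columns `ligand_conc`, `f_obs`, `f`
#'   (corrected), `a_ex`, `a_em`.
#' @export
titration_intensities <- function(series, wavelength = NULL,
                                  correct = !is.null(series$absorbance)) {
  stopifnot(inherits(series, "titration_series"))
  if (is.null(wavelength)) {
    s0 <- series$spectra[[1L]]
    wavelength <- s0$wavelength[which.max(s0$value)]
  }
  f_obs <- vapply(series$spectra, intensity_at, numeric(1L), wavelength)
  if (correct && is.null(series$absorbance))
    stop("series carries no absorbance increments; cannot correct",
         call. = FALSE)
  a_ex <- if (!is.null(series$absorbance)) series$absorbance$A_ex else
    rep(0, length(f_obs))
  a_em <- if (!is.null(series$absorbance)) series$absorbance$A_em else
    rep(0, length(f_obs))
  f <- if (correct) inner_filter_correct(f_obs, a_ex, a_em) else f_obs
  data.frame(ligand_conc = series$ligand_conc, f_obs = f_obs, f = f,
             a_ex = a_ex, a_em = a_em)
}

#' Select the linear region of a Stern-Volmer plot
#'
#' Quench titrations of serum albumin commonly show upward curvature of
#' F0/F at high quencher concentration; only the linear low-concentration
#' zone is meaningful for Stern-Volmer regression. This selector returns
#' the largest prefix of points (starting at zero quencher) whose
#' ordinary-least-squares fit has \eqn{r^2 \ge} `r2_min` and whose
#' residuals pass a sign-run curvature check (systematic convex residual
#' patterns -- few sign runs -- reject the prefix). The rule is
#' deterministic for fixed inputs. If no prefix of at least 3 points
#' qualifies, the full range is returned with a warning.
#'
#' @param conc quencher concentrations (mol/L), ascending, first entry 0.
#' @param ratio F0/F values, same length.
#' @param r2_min minimum r-squared for an acceptable prefix
#'   (default 0.995).
#' @return Integer vector of retained indices (always `1:k`).
#' @export
select_linear_region <- function(conc, ratio, r2_min = 0.995) {
  n <- length(conc)
  stopifnot(length(ratio) == n)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  scale <- mean(abs(ratio))
  for (k in n:3L) {
    x <- conc[1:k]; y <- ratio[1:k]
    fit <- stats::lm.fit(cbind(1, x), y)
    res <- fit$residuals
    ss_res <- sum(res^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    if (r2 < r2_min) next
    # sign-run curvature check: residuals above numerical noise forming
    # <= 3 runs (e.g. + - + for convex data) indicate systematic curvature
    sgn <- sign(res)
    sgn[abs(res) < 1e-8 * scale] <- 0
    nz <- sgn[sgn != 0]
    runs <- if (length(nz)) 1L + sum(diff(nz) != 0) else Inf
    if (k >= 6L && is.finite(runs) && runs <= 3L) next
    return(seq_len(k))
  }
  warning("no linear prefix of >= 3 points found; using full range")
  seq_len(n)
}

#' Stern-Volmer analysis of a quench titration
#'
#' Fits the Stern-Volmer relation \eqn{F_0/F = 1 + K_{SV}[Q]} by ordinary
#' least squares of F0/F against quencher concentration over the retained
#' linear region (see [select_linear_region()]). The slope is reported as
#' the Stern-Volmer constant \eqn{K_{SV}} (M^-1); the intercept is
#' reported but not constrained to 1 (a deviation beyond 5 percent emits
#' a warning). If the unquenched fluorophore lifetime `tau0` is supplied,
#' the bimolecular quenching constant \eqn{k_q = K_{SV}/\tau_0} is also
#' computed.
#'
#' @param conc quencher concentrations (mol/L), ascending, including 0.
#' @param f corrected fluorescence intensities at the reference
#'   wavelength, or `NULL` if `ratio` is given.
#' @param f0 unquenched intensity; defaults to `f` at zero concentration.
#' @param ratio optionally, precomputed F0/F values instead of `f`/`f0`.
#' @param tau0 unquenched fluorescence lifetime in seconds (optional;
#'   for human serum albumin 6.38e-9 s is the conventional value).
#' @param r2_min passed to [select_linear_region()].
#' @param temperature optional temperature label (degrees Celsius).
#' @return An object of class `"stern_volmer"` with components `ksv`,
#'   `intercept`, `r_squared`, `retained` (indices used), `kq`, `tau0`,
#'   `ksv_se`, `temperature` and the input data.
#' @examples
#' q <- seq(0, 22.5e-6, 1.5e-6)
#' f0 <- 1000
#' f <- f0 / (1 + 8.6e4 * q)
#' stern_volmer(q, f, tau0 = 6.38e-9)
#' @export
stern_volmer <- function(conc, f = NULL, f0 = NULL, ratio = NULL,
                         tau0 = NULL, r2_min = 0.995, temperature = NA) {
  conc <- as.numeric(conc)
  if (is.null(ratio)) {
    if (is.null(f)) stop("supply either f or ratio", call. = FALSE)
    if (is.null(f0)) {
      if (conc[1L] != 0)
        stop("f0 not given and the series does not start at [Q] = 0",
             call. = FALSE)
      f0 <- f[1L]
    }
    if (f0 <= 0 || any(f <= 0))
      stop("intensities must be positive", call. = FALSE)
    if (any(f > f0 * (1 + 1e-9)))
      warning("some intensities exceed F0; check correction")
    ratio <- f0 / f
  }
  if (length(conc) < 3L)
    stop("need at least 3 titration points", call. = FALSE)
  if (conc[1L] != 0)
    stop("the series must include the [Q] = 0 point", call. = FALSE)
  retained <- select_linear_region(conc, ratio, r2_min = r2_min)
  x <- conc[retained]; y <- ratio[retained]
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # zero-noise data: perfect fit
  ksv <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (all(abs(y - y[1L]) < 1e-12 * abs(y[1L]))) {
    warning("no quenching detected (F constant); K_SV ~ 0")
    ksv <- 0
    intercept <- y[1L]
  }
  if (abs(intercept - 1) > 0.05)
    warning(sprintf("Stern-Volmer intercept %.3f deviates from 1 by > 5%%",
                    intercept))
  kq <- if (!is.null(tau0)) {
    if (tau0 <= 0) stop("tau0 must be positive", call. = FALSE)
    ksv / tau0
  } else NA_real_
  structure(list(ksv = ksv, intercept = intercept,
                 r_squared = sm$r.squared,
                 ksv_se = sm$coefficients[2L, 2L],
                 retained = retained, kq = kq,
                 tau0 = if (is.null(tau0)) NA_real_ else tau0,
                 temperature = temperature,
                 conc = conc, ratio = ratio),
            class = "stern_volmer")
}

#' @export
print.stern_volmer <- function(x, ...) {
  cat("Stern-Volmer analysis\n")
  if (!is.na(x$temperature))
    cat(sprintf("  temperature: %g degC\n", x$temperature))
  cat(sprintf("  K_SV      = %s M^-1  (SE %s)\n",
              fmt_sci(x$ksv), fmt_sci(x$ksv_se)))
  cat(sprintf("  intercept = %.4f\n", x$intercept))
  cat(sprintf("  r^2       = %.5f over %d/%d points\n",
              x$r_squared, length(x$retained), length(x$conc)))
  if (!is.na(x$kq))
    cat(sprintf("  k_q       = %s M^-1 s^-1  (tau0 = %s s)\n",
                fmt_sci(x$kq), fmt_sci(x$tau0)))
  invisible(x)
}

#' @export
coef.stern_volmer <- function(object, ...) {
  c(K_SV = object$ksv, intercept = object$intercept)
}

#' @export
plot.stern_volmer <- function(x, ...) {
  graphics::plot(x$conc * 1e6, x$ratio, xlab = "[Q] (uM)",
                 ylab = expression(F[0] / F), ...)
  graphics::points(x$conc[x$retained] * 1e6, x$ratio[x$retained], pch = 16)
  graphics::abline(x$intercept, x$ksv * 1e-6)
  invisible(x)
}

#' Bimolecular quenching constant
#'
#' \eqn{k_q = K_{SV} / \tau_0}. Values above the diffusion-controlled
#' limit (~1e10 M^-1 s^-1) indicate ground-state complex formation
#' (static quenching) rather than collisional quenching.
#'
#' @param ksv Stern-Volmer constant (M^-1).
#' @param tau0 unquenched fluorophore lifetime (s, > 0).
#' @return k_q in M^-1 s^-1.
#' @export
bimolecular_quenching <- function(ksv, tau0) {
  if (any(tau0 <= 0)) stop("tau0 must be positive", call. = FALSE)
  ksv / tau0
}

#' Classify the quenching mechanism from the temperature trend of K_SV
#'
#' Static quenching (ground-state complex) weakens with temperature, so
#' K_SV decreases as T rises; collisional (dynamic) quenching does the
#' opposite. The classifier labels a set of per-temperature Stern-Volmer
#' results `"static"` if K_SV strictly decreases with temperature,
#' `"dynamic"` if it strictly increases, and `"ambiguous"` otherwise,
#' and reports whether the smallest k_q exceeds the diffusion limit.
#'
#' @param fits list of [stern_volmer()] results, or a numeric vector of
#'   K_SV values.
#' @param temperature temperatures (degrees Celsius) matching `fits`;
#'   taken from the fits when omitted.
#' @param tau0 lifetime used to derive k_q when `fits` is numeric.
#' @param diffusion_limit threshold for the k_q check (default 1e10
#'   M^-1 s^-1).
#' @return An object of class `"quench_classification"`.
#' @export
classify_quenching <- function(fits, temperature = NULL, tau0 = NULL,
                               diffusion_limit = 1e10) {
  if (is.list(fits)) {
    ksv <- vapply(fits, function(f) f$ksv, numeric(1L))
    kq <- vapply(fits, function(f) f$kq, numeric(1L))
    if (is.null(temperature))
      temperature <- vapply(fits, function(f) f$temperature, numeric(1L))
  } else {
    ksv <- as.numeric(fits)
    kq <- if (!is.null(tau0)) ksv / tau0 else rep(NA_real_, length(ksv))
  }
  if (length(ksv) < 2L)
    stop("need Stern-Volmer results at >= 2 temperatures", call. = FALSE)
  if (is.null(temperature) || anyNA(temperature))
    stop("temperatures are required for classification", call. = FALSE)
  ord <- order(temperature)
  ksv <- ksv[ord]; kq <- kq[ord]; temperature <- temperature[ord]
  label <- if (all(diff(ksv) < 0)) "static"
           else if (all(diff(ksv) > 0)) "dynamic"
           else "ambiguous"
  above <- if (all(is.na(kq))) NA else min(kq, na.rm = TRUE) > diffusion_limit
  structure(list(label = label, temperature = temperature, ksv = ksv,
                 kq = kq, above_diffusion_limit = above,
                 diffusion_limit = diffusion_limit),
            class = "quench_classification")
}

#' @export
print.quench_classification <- function(x, ...) {
  cat(sprintf("Quenching mechanism: %s\n", x$label))
  tab <- data.frame(temperature_C = x$temperature,
                    K_SV = fmt_sci(x$ksv),
                    k_q = ifelse(is.na(x$kq), "-", fmt_sci(x$kq)))
  print(tab, row.names = FALSE)
  if (!is.na(x$above_diffusion_limit))
    cat(sprintf("  min k_q %s the diffusion limit (%s M^-1 s^-1)\n",
                if (x$above_diffusion_limit) "exceeds" else "is below",
                fmt_sci(x$diffusion_limit, 1)))
  invisible(x)
}
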