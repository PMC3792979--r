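#' Association constant and stoichiometry from the double-logarithmic
#' binding isotherm
#'
#' Fits the mass-balance-corrected double-logarithmic model
#' \deqn{\log_{10}\frac{F_0 - F}{F} = n \log_{10} K_a +
#'       n \log_{10}\left([D_T] - \frac{F_0 - F}{F_0}[P_T]\right)}
#' in which the free ligand concentration is obtained from total ligand
#' \eqn{[D_T]} by subtracting the bound-ligand estimate
#' (occupancy x \eqn{[P_T]}), with the fractional quench
#' \eqn{(F_0-F)/F_0} taken as the fractional saturation of binding
#' sites. Unlike the naive double-log plot against total ligand, this
#' form makes no assumption that ligand is in large excess. The slope is
#' the binding stoichiometry `n` and \eqn{K_a = 10^{intercept/slope}}.
#'
#' The occupancy proxy assumes the quench depth at saturation is complete
#' (fluorophore fully quenched in the complex); partial quench depths
#' bias \eqn{K_a} downward -- see the package vignette.
#'
#' @param x a [titration_series()] or a numeric vector of total ligand
#'   concentrations (mol/L).
#' @param ... passed between methods.
#' @return An object of class `"binding_fit"` with components `ka`, `n`,
#'   `r_squared`, `log10_ka_se`, `n_se`, `points_used`, `temperature`.
#' @examples
#' d <- seq(0, 22.5e-6, 1.5e-6)
#' pd <- equilibrium_1to1(3e-6, d, 1.03e5)
#' f <- 1000 * (1 - pd / 3e-6)
#' binding_isotherm(d, f = f, protein_conc = 3e-6)
#' @export
binding_isotherm <- function(x, ...) UseMethod("binding_isotherm")

#' @rdname binding_isotherm
#' @param f corrected fluorescence intensities at the reference
#'   wavelength, one per ligand concentration.
#' @param f0 unquenched intensity; defaults to `f` at zero ligand.
#' @param protein_conc total protein concentration (mol/L).
#' @param temperature optional temperature label (degrees Celsius).
#' @export
binding_isotherm.default <- function(x, f, f0 = NULL, protein_conc,
                                     temperature = NA, ...) {
  d_total <- as.numeric(x)
  if (is.null(f0)) {
    if (d_total[1L] != 0)
      stop("f0 not given and the series does not start at zero ligand",
           call. = FALSE)
    f0 <- f[1L]
  }
  if (f0 <= 0) stop("f0 must be positive", call. = FALSE)
  quenched <- is.finite(f) & f < f0 & f > 0 & d_total > 0
  if (all(f >= f0))
    stop("no binding signal: F never falls below F0", call. = FALSE)
  occupancy <- (f0 - f) / f0
  d_free <- d_total - occupancy * protein_conc
  usable <- quenched & d_free > 0
  if (any(quenched & d_free <= 0))
    warning(sprintf(
      "%d point(s) dropped: mass-balance free-ligand estimate <= 0",
      sum(quenched & d_free <= 0)))
  if (sum(usable) < 4L)
    stop(sprintf("need >= 4 usable points with F < F0 (have %d)",
                 sum(usable)), call. = FALSE)
  y <- log10((f0 - f[usable]) / f[usable])
  xx <- log10(d_free[usable])
  fit <- stats::lm(y ~ xx)
  sm <- suppressWarnings(summary(fit))  # zero-noise data: perfect fit
  n <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (n <= 0) stop("fitted stoichiometry is non-positive", call. = FALSE)
  log10_ka <- intercept / n
  structure(list(ka = 10^log10_ka, n = n, r_squared = sm$r.squared,
                 n_se = sm$coefficients[2L, 2L],
                 log10_ka_se = sm$coefficients[1L, 2L] / n,
                 points_used = which(usable),
                 temperature = temperature,
                 data = data.frame(log_free = xx, log_ratio = y)),
            class = "binding_fit")
}

#' @rdname binding_isotherm
#' @param wavelength reference wavelength (nm); default is the emission
#'   maximum of the ligand-free spectrum.
#' @param correct apply the series' inner-filter correction before
#'   fitting (default: yes if absorbance increments are stored).
#' @export
binding_isotherm.titration_series <- function(x, wavelength = NULL,
    correct = !is.null(x$absorbance), ...) {
  intens <- titration_intensities(x, wavelength = wavelength,
                                  correct = correct)
  binding_isotherm(intens$ligand_conc, f = intens$f,
                   protein_conc = x$protein_conc,
                   temperature = x$temperature, ...)
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("Double-logarithmic binding isotherm\n")
  if (!is.na(x$temperature))
    cat(sprintf("  temperature: %g degC\n", x$temperature))
  cat(sprintf("  K_a = %s M^-1\n", fmt_sci(x$ka)))
  cat(sprintf("  n   = %.3f  (SE %.3f)\n", x$n, x$n_se))
  cat(sprintf("  r^2 = %.5f over %d points\n", x$r_squared,
              length(x$points_used)))
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) {
  c(K_a = object$ka, n = object$n)
}

#' @export
summary.binding_fit <- function(object, ...) {
  out <- data.frame(estimate = c(object$ka, object$n),
                    se = c(object$ka * log(10) * object$log10_ka_se,
                           object$n_se),
                    row.names = c("K_a", "n"))
  cat(sprintf("Binding isotherm fit (%d points, r^2 = %.5f)\n",
              length(object$points_used), object$r_squared))
  print(out)
  invisible(out)
}

#' @export
plot.binding_fit <- function(x, ...) {
  graphics::plot(x$data$log_free, x$data$log_ratio,
                 xlab = expression(log[10] ~ "[D]"[free]),
                 ylab = expression(log[10] ~ (F[0] - F) / F), ...)
  graphics::abline(stats::lm(log_ratio ~ log_free, data = x$data))
  invisible(x)
}
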