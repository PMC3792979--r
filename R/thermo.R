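# gas constant, J mol^-1 K^-1
GAS_CONSTANT <- 8.314

#' Celsius to kelvin
#'
#' @param t temperature in degrees Celsius.
#' @param offset additive offset; 273.15 by default. Some published
#'   tables are computed with the rounded offset 273 -- pass
#'   `offset = 273` to reproduce such values at their printed precision.
#' @export
celsius_to_kelvin <- function(t, offset = 273.15) t + offset

#' Van't Hoff decomposition of the binding free energy
#'
#' Ordinary least squares of \eqn{\ln K_a} against \eqn{1/T}:
#' \deqn{\ln K = -\frac{\Delta H}{R T} + \frac{\Delta S}{R}}
#' so \eqn{\Delta H = -R \cdot slope} and \eqn{\Delta S = R \cdot
#' intercept}, both treated as temperature-independent over the range
#' studied (no heat-capacity correction). The Gibbs energy at each input
#' temperature follows from [gibbs_energy()].
#'
#' @param ka association constants (M^-1), all positive.
#' @param temperature matching temperatures; kelvin by default.
#' @param unit `"K"` or `"C"`; Celsius inputs are converted with
#'   `kelvin_offset`.
#' @param kelvin_offset see [celsius_to_kelvin()].
#' @return An object of class `"vant_hoff"` with `delta_H` (kJ mol^-1),
#'   `delta_S` (J mol^-1 K^-1), `r_squared`, and `delta_G` (kJ mol^-1,
#'   named by temperature in K).
#' @examples
#' ka <- c(1.28e5, 1.03e5, 8.57e4, 6.92e4)
#' vant_hoff(ka, c(15, 25, 35, 45), unit = "C", kelvin_offset = 273)
#' @export
vant_hoff <- function(ka, temperature, unit = c("K", "C"),
                      kelvin_offset = 273.15) {
  unit <- match.arg(unit)
  if (length(ka) != length(temperature))
    stop("ka and temperature must have equal length", call. = FALSE)
  if (length(ka) < 2L)
    stop("need association constants at >= 2 temperatures", call. = FALSE)
  if (any(ka <= 0)) stop("association constants must be positive",
                         call. = FALSE)
  t_k <- if (unit == "C") celsius_to_kelvin(temperature, kelvin_offset)
         else as.numeric(temperature)
  if (anyDuplicated(t_k)) stop("duplicate temperatures", call. = FALSE)
  inv_t <- 1 / t_k
  fit <- stats::lm(log(ka) ~ inv_t)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  r2 <- if (length(ka) > 2L)
    suppressWarnings(summary(fit))$r.squared else 1  # exact data: perfect fit
  delta_H <- -GAS_CONSTANT * slope / 1000       # kJ mol^-1
  delta_S <- GAS_CONSTANT * intercept           # J mol^-1 K^-1
  delta_G <- gibbs_energy(delta_H, delta_S, t_k)
  names(delta_G) <- format(t_k)
  structure(list(delta_H = delta_H, delta_S = delta_S,
                 r_squared = r2, slope = slope, intercept = intercept,
                 temperature_K = t_k, ka = ka, delta_G = delta_G,
                 gas_constant = GAS_CONSTANT),
            class = "vant_hoff")
}

#' Gibbs free energy from enthalpy and entropy
#'
#' \eqn{\Delta G = \Delta H - T \Delta S} with the mixed units
#' conventional in binding studies (\eqn{\Delta H}, \eqn{\Delta G} in
#' kJ mol^-1; \eqn{\Delta S} in J mol^-1 K^-1).
#'
#' @param delta_H enthalpy change, kJ mol^-1.
#' @param delta_S entropy change, J mol^-1 K^-1.
#' @param temperature_K absolute temperature(s), K.
#' @return Gibbs energy in kJ mol^-1 (vectorized over temperature).
#' @examples
#' gibbs_energy(-15.48, 44.06, 288)   # -28.17
#' @export
gibbs_energy <- function(delta_H, delta_S, temperature_K) {
  delta_H - temperature_K * delta_S / 1000
}

#' @export
print.vant_hoff <- function(x, ...) {
  cat("van't Hoff analysis\n")
  cat(sprintf("  delta_H = %+.2f kJ mol^-1\n", x$delta_H))
  cat(sprintf("  delta_S = %+.2f J mol^-1 K^-1\n", x$delta_S))
  cat(sprintf("  r^2     = %.5f (%d temperatures)\n", x$r_squared,
              length(x$temperature_K)))
  tab <- data.frame(T_K = x$temperature_K, K_a = fmt_sci(x$ka),
                    delta_G_kJ = sprintf("%+.2f", x$delta_G))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.vant_hoff <- function(object, ...) {
  c(delta_H = object$delta_H, delta_S = object$delta_S)
}

#' Predict ln K, K and Gibbs energy at new temperatures
#'
#' @param object a [vant_hoff()] fit.
#' @param temperature_K temperatures (K); defaults to the fitted ones.
#' @param ... ignored.
#' @return Data frame with `temperature_K`, `ln_ka`, `ka`, `delta_G`.
#' @export
predict.vant_hoff <- function(object, temperature_K = NULL, ...) {
  if (is.null(temperature_K)) temperature_K <- object$temperature_K
  ln_ka <- object$intercept + object$slope / temperature_K
  data.frame(temperature_K = temperature_K, ln_ka = ln_ka,
             ka = exp(ln_ka),
             delta_G = gibbs_energy(object$delta_H, object$delta_S,
                                    temperature_K))
}

#' @export
plot.vant_hoff <- function(x, ...) {
  graphics::plot(1 / x$temperature_K, log(x$ka),
                 xlab = "1/T (K^-1)", ylab = "ln K", ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}
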