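# Forster resonance energy transfer between the protein donor (Trp) and
# a bound ligand acceptor. Unit conventions: J in M^-1 cm^-1 nm^4
# internally; 1 M^-1 cm^3 = 1e28 M^-1 cm^-1 nm^4. The R0 formula with
# J in M^-1 cm^-1 nm^4 yields R0 in Angstrom:
#   R0^6 (A^6) = 8.79e-5 * kappa^2 * n^-4 * Q_D * J

J_CM3_TO_NM4 <- 1e28

#' Spectral overlap integral between donor emission and acceptor
#' absorption
#'
#' \deqn{J = \frac{\int F_D(\lambda)\,\varepsilon_A(\lambda)\,
#'   \lambda^4\, d\lambda}{\int F_D(\lambda)\, d\lambda}}
#' evaluated by the trapezoidal rule on the union of the two wavelength
#' grids (linear interpolation) over the common support. The
#' normalization by the donor integral makes J invariant under rescaling
#' of the donor intensity.
#'
#' @param donor donor emission [spectrum()] (arbitrary units).
#' @param acceptor acceptor molar extinction [spectrum()], values in
#'   M^-1 cm^-1 (see [molar_extinction()]).
#' @return Overlap integral J in M^-1 cm^-1 nm^4. Zero with a warning if
#'   the spectra do not overlap.
#' @export
overlap_integral <- function(donor, acceptor) {
  stopifnot(inherits(donor, "spectrum"), inherits(acceptor, "spectrum"))
  grid <- union_grid(donor$wavelength, acceptor$wavelength)
  if (!length(grid)) {
    warning("donor and acceptor spectra do not overlap; J = 0")
    return(0)
  }
  fd <- intensity_at(donor, grid)
  eps <- intensity_at(acceptor, grid)
  denom <- trapz(donor$wavelength, donor$value)
  if (denom <= 0) stop("donor spectrum integrates to zero", call. = FALSE)
  trapz(grid, fd * eps * grid^4) / denom
}

#' Convert an absorbance spectrum to molar extinction
#'
#' \eqn{\varepsilon(\lambda) = A(\lambda) / (l \cdot c)} (Beer-Lambert).
#' Path length and concentration may be supplied as arguments or carried
#' in the spectrum metadata (`path_cm`, `conc_M`); absence is an error.
#'
#' @param absorbance an absorbance [spectrum()].
#' @param path_cm cuvette path length in cm.
#' @param conc_M chromophore concentration in mol/L.
#' @return A [spectrum()] of kind `"absorbance"` whose values are molar
#'   extinction coefficients (M^-1 cm^-1).
#' @export
molar_extinction <- function(absorbance, path_cm = NULL, conc_M = NULL) {
  stopifnot(inherits(absorbance, "spectrum"))
  if (is.null(path_cm)) path_cm <- absorbance$meta$path_cm
  if (is.null(conc_M)) conc_M <- absorbance$meta$conc_M
  if (is.null(path_cm) || is.null(conc_M))
    stop("path_cm and conc_M are required (argument or spectrum meta)",
         call. = FALSE)
  if (path_cm <= 0 || conc_M <= 0)
    stop("path length and concentration must be positive", call. = FALSE)
  spectrum(absorbance$wavelength, absorbance$value / (path_cm * conc_M),
           kind = "absorbance",
           meta = c(absorbance$meta, list(unit = "M-1 cm-1")))
}

#' Forster critical distance
#'
#' The donor-acceptor separation at which transfer efficiency is 50
#' percent: \eqn{R_0^6 = 8.79\times 10^{-5} \kappa^2 n^{-4} Q_D J}
#' (result in Angstrom^6 with J in M^-1 cm^-1 nm^4), returned in nm.
#'
#' @param j overlap integral; unit given by `j_unit`.
#' @param kappa2 orientation factor of the transition dipoles (2/3 for
#'   random averaging).
#' @param refractive_index refractive index of the medium (1.336 for
#'   dilute aqueous solutions).
#' @param quantum_yield donor fluorescence quantum yield in the absence
#'   of acceptor (0.118 for native human serum albumin).
#' @param j_unit `"M-1 cm-1 nm4"` (default) or `"M-1 cm3"`
#'   (converted by the factor 1e28).
#' @return R0 in nm.
#' @examples
#' forster_radius(2.814e-15, j_unit = "M-1 cm3")   # ~1.98 nm
#' @export
forster_radius <- function(j, kappa2 = 2 / 3, refractive_index = 1.336,
                           quantum_yield = 0.118,
                           j_unit = c("M-1 cm-1 nm4", "M-1 cm3")) {
  j_unit <- match.arg(j_unit)
  if (j < 0) stop("J must be non-negative", call. = FALSE)
  if (j == 0) return(0)
  if (kappa2 <= 0 || kappa2 > 4)
    stop("kappa2 must lie in (0, 4]", call. = FALSE)
  if (quantum_yield <= 0 || quantum_yield > 1)
    stop("quantum_yield must lie in (0, 1]", call. = FALSE)
  if (refractive_index <= 0)
    stop("refractive_index must be positive", call. = FALSE)
  j_nm4 <- if (j_unit == "M-1 cm3") j * J_CM3_TO_NM4 else j
  r0_A6 <- 8.79e-5 * kappa2 * refractive_index^-4 * quantum_yield * j_nm4
  r0_A6^(1 / 6) / 10
}

#' Energy-transfer efficiency from quenched and unquenched intensities
#'
#' \eqn{E = 1 - F/F_0}.
#'
#' @param f donor intensity in the presence of the acceptor.
#' @param f0 donor intensity in the absence of the acceptor.
#' @export
transfer_efficiency <- function(f, f0) {
  if (any(f0 <= 0)) stop("f0 must be positive", call. = FALSE)
  1 - f / f0
}

#' Donor-acceptor distance from efficiency and Forster radius
#'
#' Inverts \eqn{E = R_0^6 / (R_0^6 + r^6)}:
#' \eqn{r = R_0 ((1 - E)/E)^{1/6}}.
#'
#' @param e transfer efficiency, strictly between 0 and 1.
#' @param r0 Forster radius (nm).
#' @return Distance r in nm.
#' @examples
#' donor_acceptor_distance(0.214, 1.983)   # ~2.46 nm
#' @export
donor_acceptor_distance <- function(e, r0) {
  if (any(e <= 0 | e >= 1))
    stop("efficiency must lie strictly between 0 and 1", call. = FALSE)
  r0 * ((1 - e) / e)^(1 / 6)
}

#' Full FRET analysis
#'
#' Chains [overlap_integral()], [forster_radius()],
#' [transfer_efficiency()] and [donor_acceptor_distance()] and attaches
#' the standard validity checks.
#'
#' @param donor donor emission [spectrum()].
#' @param acceptor acceptor [spectrum()]: either molar extinction
#'   (M^-1 cm^-1) directly, or an absorbance spectrum to be converted
#'   via `path_cm`/`conc_M` (arguments or spectrum metadata).
#' @param f_ratio F/F0 of the donor at the 1:1 donor:acceptor point,
#'   in (0, 1].
#' @inheritParams forster_radius
#' @param path_cm,conc_M passed to [molar_extinction()] when the
#'   acceptor spectrum is raw absorbance.
#' @param acceptor_is_extinction set `TRUE` when `acceptor` already
#'   holds molar extinction values.
#' @return An object of class `"fret_result"` with `j_nm4`, `j_cm3`,
#'   `e`, `r0`, `r`, and logical validity flags `valid_half_to_double`
#'   (0.5 R0 < r < 2 R0) and `valid_2_to_8nm` (2 nm < r < 8 nm).
#' @export
fret_analysis <- function(donor, acceptor, f_ratio, kappa2 = 2 / 3,
                          refractive_index = 1.336, quantum_yield = 0.118,
                          path_cm = NULL, conc_M = NULL,
                          acceptor_is_extinction = FALSE) {
  if (f_ratio <= 0 || f_ratio > 1)
    stop("f_ratio must lie in (0, 1]", call. = FALSE)
  eps <- if (acceptor_is_extinction) acceptor
         else molar_extinction(acceptor, path_cm = path_cm, conc_M = conc_M)
  j <- overlap_integral(donor, eps)
  r0 <- forster_radius(j, kappa2 = kappa2,
                       refractive_index = refractive_index,
                       quantum_yield = quantum_yield)
  e <- transfer_efficiency(f_ratio, 1)
  r <- donor_acceptor_distance(e, r0)
  validate_fret(r0, r, j = j, e = e)
}

#' Validity report for a FRET distance determination
#'
#' Checks the standard reliability criteria: `0.5 R0 < r < 2 R0` and
#' `2 nm < r < 8 nm`, and notes whether `r > R0` (consistent with a
#' static quenching mechanism, where efficiency at the 1:1 point is
#' below 50 percent).
#'
#' @param r0 Forster radius (nm), or a `"fret_result"` object.
#' @param r donor-acceptor distance (nm).
#' @param j,e optional overlap integral and efficiency to carry along.
#' @return An object of class `"fret_result"`.
#' @export
validate_fret <- function(r0, r = NULL, j = NA_real_, e = NA_real_) {
  if (inherits(r0, "fret_result")) {
    obj <- r0
    r <- obj$r; j <- obj$j_nm4; e <- obj$e; r0 <- obj$r0
  }
  structure(list(j_nm4 = j, j_cm3 = j / J_CM3_TO_NM4, e = e,
                 r0 = r0, r = r,
                 valid_half_to_double = (r > 0.5 * r0) && (r < 2 * r0),
                 valid_2_to_8nm = (r > 2) && (r < 8),
                 r_exceeds_r0 = r > r0),
            class = "fret_result")
}

#' @export
print.fret_result <- function(x, ...) {
  cat("FRET analysis\n")
  if (is.finite(x$j_nm4))
    cat(sprintf("  J  = %s M^-1 cm^-1 nm^4  (%s M^-1 cm^3)\n",
                fmt_sci(x$j_nm4), fmt_sci(x$j_cm3)))
  if (is.finite(x$e)) cat(sprintf("  E  = %.3f\n", x$e))
  cat(sprintf("  R0 = %.3f nm\n", x$r0))
  cat(sprintf("  r  = %.3f nm\n", x$r))
  cat(sprintf("  0.5 R0 < r < 2 R0 : %s\n",
              if (x$valid_half_to_double) "pass" else "FAIL"))
  cat(sprintf("  2 nm < r < 8 nm   : %s\n",
              if (x$valid_2_to_8nm) "pass" else "FAIL"))
  if (isTRUE(x$r_exceeds_r0))
    cat("  r > R0: consistent with a static quenching mechanism\n")
  invisible(x)
}
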