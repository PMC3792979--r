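# Site-marker displacement: loss of a marker ligand's induced optical
# signal upon competitor addition, used to assign the competitor's
# binding site on serum albumin (site I markers: warfarin, bilirubin;
# site II markers: diazepam, ketoprofen).

#' Relative signal of a displacement titration
#'
#' Normalizes raw signals to the competitor-free (first) value, in
#' percent, preserving sign. Optionally subtracts a baseline first --
#' e.g. the competitor-protein complex's own spectral contribution at
#' the monitoring wavelength, which otherwise confounds the marker
#' signal.
#'
#' @param signal raw signal values, first entry at molar ratio 0.
#' @param baseline optional baseline (scalar or per-point vector) to
#'   subtract before normalization.
#' @return Numeric vector of relative signals in percent (first entry
#'   100).
#' @export
relative_signal <- function(signal, baseline = NULL) {
  if (!is.null(baseline)) signal <- signal - baseline
  if (signal[1L] == 0)
    stop("signal at ratio 0 is zero; cannot normalize", call. = FALSE)
  100 * signal / signal[1L]
}

#' Construct a displacement series
#'
#' @param marker marker ligand name (e.g. `"WFN"`, `"BR"`, `"DZM"`,
#'   `"KTN"`).
#' @param site the marker's known binding site, `"I"` or `"II"`.
#' @param ratio competitor/protein molar ratios, ascending from 0.
#' @param signal raw optical signal at each ratio (induced CD or
#'   fluorescence of the marker-protein complex).
#' @param signal_wavelength monitoring wavelength (nm, informational).
#' @param baseline optional baseline passed to [relative_signal()].
#' @return An object of class `"displacement_series"`.
#' @export
displacement_series <- function(marker, site = c("I", "II"), ratio,
                                signal, signal_wavelength = NA,
                                baseline = NULL) {
  site <- match.arg(site)
  ratio <- as.numeric(ratio)
  if (ratio[1L] != 0)
    stop("the series must start at molar ratio 0", call. = FALSE)
  check_strictly_increasing(ratio, "ratio")
  if (length(signal) != length(ratio))
    stop("signal and ratio must have equal length", call. = FALSE)
  structure(list(marker = marker, site = site, ratio = ratio,
                 signal = as.numeric(signal),
                 relative_percent = relative_signal(signal, baseline),
                 signal_wavelength = signal_wavelength),
            class = "displacement_series")
}

#' @export
print.displacement_series <- function(x, ...) {
  cat(sprintf("<displacement_series: %s (site %s), ratios 0-%g, final %.1f%%>\n",
              x$marker, x$site, max(x$ratio),
              x$relative_percent[length(x$ratio)]))
  invisible(x)
}

#' Percent signal loss at a molar ratio
#'
#' `100 - relative signal`, linearly interpolated at the requested
#' competitor/protein ratio. Ratios beyond the measured grid are an
#' error.
#'
#' @param series a [displacement_series()].
#' @param ratio molar ratio(s) at which to evaluate the loss.
#' @return Percent loss (0 at ratio 0).
#' @export
displacement_at_ratio <- function(series, ratio) {
  stopifnot(inherits(series, "displacement_series"))
  if (any(ratio < 0 | ratio > max(series$ratio)))
    stop(sprintf("ratio outside measured range [0, %g]",
                 max(series$ratio)), call. = FALSE)
  100 - stats::approx(series$ratio, series$relative_percent,
                      xout = ratio, ties = "ordered")$y
}

#' Assign the competitor's binding site from marker displacement
#'
#' A site is assigned when the maximum signal loss of *every* marker
#' probing that site exceeds `threshold` while all markers of the other
#' site stay below it; if both sites qualify the verdict is `"both"`,
#' and `"indeterminate"` otherwise. The per-marker loss table always
#' accompanies the verdict so other decision rules can be applied.
#'
#' @param site1 list of [displacement_series()] for site I markers
#'   (or a single series).
#' @param site2 list of [displacement_series()] for site II markers.
#' @param threshold percent-loss threshold for displacement
#'   (default 50).
#' @param ratio molar ratio at which losses are compared; default the
#'   largest ratio common to all series.
#' @return An object of class `"site_assignment"` with `verdict` in
#'   `{"site I", "site II", "both", "indeterminate"}` and a `table` of
#'   per-marker losses.
#' @export
assign_site <- function(site1, site2, threshold = 50, ratio = NULL) {
  if (inherits(site1, "displacement_series")) site1 <- list(site1)
  if (inherits(site2, "displacement_series")) site2 <- list(site2)
  if (!length(site1) || !length(site2))
    stop("need at least one marker series per site", call. = FALSE)
  all_series <- c(site1, site2)
  if (is.null(ratio))
    ratio <- min(vapply(all_series, function(s) max(s$ratio), numeric(1L)))
  loss <- vapply(all_series, displacement_at_ratio, numeric(1L), ratio)
  tab <- data.frame(
    marker = vapply(all_series, `[[`, character(1L), "marker"),
    site = vapply(all_series, `[[`, character(1L), "site"),
    loss_percent = loss)
  i_1 <- seq_along(site1)
  displaced1 <- all(loss[i_1] > threshold) &&
    all(loss[-i_1] < threshold)
  displaced2 <- all(loss[-i_1] > threshold) &&
    all(loss[i_1] < threshold)
  both <- all(loss > threshold)
  verdict <- if (both) "both"
             else if (displaced1) "site I"
             else if (displaced2) "site II"
             else "indeterminate"
  structure(list(verdict = verdict, table = tab, ratio = ratio,
                 threshold = threshold),
            class = "site_assignment")
}

#' @export
print.site_assignment <- function(x, ...) {
  cat(sprintf("Binding-site assignment at molar ratio %g (threshold %g%%)\n",
              x$ratio, x$threshold))
  print(transform(x$table, loss_percent = round(loss_percent, 1)),
        row.names = FALSE)
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}
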