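# Conformational-change metrics: synchronous fluorescence shifts, EEM
# peak detection, mean residue ellipticity, and thermal melt recovery.

# parabolic refinement of a discrete argmax: fits a parabola through the
# three points around the maximum and returns the interpolated apex
refine_peak <- function(wavelength, value) {
  i <- which.max(value)
  n <- length(value)
  if (diff(range(value)) == 0)
    stop("flat signal: no unique maximum", call. = FALSE)
  if (i == 1L || i == n)
    return(list(peak = wavelength[i], discrete = wavelength[i],
                intensity = value[i]))
  x <- wavelength[(i - 1L):(i + 1L)]
  y <- value[(i - 1L):(i + 1L)]
  denom <- (y[1L] - 2 * y[2L] + y[3L])
  if (denom >= 0)            # degenerate: not locally concave
    return(list(peak = wavelength[i], discrete = wavelength[i],
                intensity = value[i]))
  # vertex of the parabola through the three bracketing points
  d <- 0.5 * (y[1L] - y[3L]) / denom
  h <- x[2L] - x[1L]   # grids local to 3 points; assume near-uniform
  list(peak = x[2L] + d * h, discrete = wavelength[i],
       intensity = y[2L] - 0.25 * (y[1L] - y[3L]) * d)
}

#' Synchronous fluorescence peak shift across a titration
#'
#' Synchronous scans with a fixed excitation-emission offset report on
#' the microenvironment of tyrosine (offset 15 nm) or tryptophan
#' (offset 60 nm) residues; a blue shift of the peak with increasing
#' ligand indicates a move to a less polar milieu. The peak of each
#' spectrum is located by 3-point parabolic refinement of the discrete
#' maximum, and the net shift is the last peak minus the first
#' (negative = blue shift).
#'
#' @param spectra list of synchronous [spectrum()]s in titration order.
#' @param delta_lambda the scan offset in nm (15 or 60, informational);
#'   checked against the spectra's `delta_lambda` metadata when present.
#' @return An object of class `"sync_shift"`: per-spectrum peak table
#'   and `net_shift` (nm).
#' @export
synchronous_shift <- function(spectra, delta_lambda = NULL) {
  stopifnot(length(spectra) >= 1L)
  tags <- lapply(spectra, function(s) s$meta$delta_lambda)
  tags <- unlist(tags[!vapply(tags, is.null, logical(1L))])
  if (length(tags) && length(unique(tags)) > 1L)
    stop("spectra carry inconsistent delta_lambda tags", call. = FALSE)
  if (!is.null(delta_lambda) && length(tags) &&
      any(tags != delta_lambda))
    stop(sprintf("spectra are tagged delta_lambda = %g, not %g",
                 tags[1L], delta_lambda), call. = FALSE)
  peaks <- lapply(spectra, function(s) refine_peak(s$wavelength, s$value))
  tab <- data.frame(
    index = seq_along(spectra),
    peak_nm = vapply(peaks, `[[`, numeric(1L), "peak"),
    discrete_peak_nm = vapply(peaks, `[[`, numeric(1L), "discrete"),
    intensity = vapply(peaks, `[[`, numeric(1L), "intensity"))
  structure(list(peaks = tab,
                 net_shift = tab$peak_nm[nrow(tab)] - tab$peak_nm[1L],
                 delta_lambda = if (length(tags)) tags[1L] else
                   delta_lambda),
            class = "sync_shift")
}

#' @export
print.sync_shift <- function(x, ...) {
  cat(sprintf("Synchronous fluorescence shift (delta lambda = %s nm)\n",
              if (is.null(x$delta_lambda)) "?" else x$delta_lambda))
  cat(sprintf("  peak: %.2f -> %.2f nm, net shift %+.2f nm (%s)\n",
              x$peaks$peak_nm[1L], x$peaks$peak_nm[nrow(x$peaks)],
              x$net_shift,
              if (x$net_shift < 0) "blue" else if (x$net_shift > 0)
                "red" else "none"))
  invisible(x)
}

#' Detect and classify peaks of an excitation-emission matrix
#'
#' Local maxima of the intensity surface (8-neighbourhood). Maxima on
#' the Rayleigh scatter ridge (emission = excitation, within
#' `scatter_tol`) are labelled `rayleigh_a`; maxima on the second-order
#' scatter ridge (emission = 2 x excitation) are labelled
#' `second_order_b`. The remaining maxima are ranked by intensity and
#' labelled `peak1`, `peak2`, then `other` -- for serum albumin, peak 1
#' (excitation ~280 nm) reports on Trp/Tyr fluorescence and peak 2
#' (excitation ~235 nm) on the polypeptide backbone.
#'
#' @param surface an [eem_surface()].
#' @param scatter_tol scatter-ridge tolerance in nm (default 5).
#' @return Data frame with columns `excitation`, `emission`,
#'   `intensity`, `label`, ordered scatter ridges last, protein peaks
#'   by decreasing intensity.
#' @export
find_3d_peaks <- function(surface, scatter_tol = 5) {
  stopifnot(inherits(surface, "eem_surface"))
  m <- surface$intensity
  nr <- nrow(m); nc <- ncol(m)
  peaks <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- m[i, j]
    nb <- m[max(1L, i - 1L):min(nr, i + 1L),
            max(1L, j - 1L):min(nc, j + 1L)]
    if (v > max(nb[nb != v], -Inf) && sum(nb == v) == 1L)
      peaks[[length(peaks) + 1L]] <-
        c(ex = surface$excitation[i], em = surface$emission[j], int = v)
  }
  if (!length(peaks))
    return(data.frame(excitation = numeric(0), emission = numeric(0),
                      intensity = numeric(0), label = character(0)))
  tab <- as.data.frame(do.call(rbind, peaks))
  names(tab) <- c("excitation", "emission", "intensity")
  is_rayleigh <- abs(tab$emission - tab$excitation) <= scatter_tol
  is_second <- abs(tab$emission - 2 * tab$excitation) <= scatter_tol &
    !is_rayleigh
  tab$label <- "other"
  tab$label[is_rayleigh] <- "rayleigh_a"
  tab$label[is_second] <- "second_order_b"
  protein <- which(tab$label == "other")
  protein <- protein[order(-tab$intensity[protein])]
  if (length(protein) >= 1L) tab$label[protein[1L]] <- "peak1"
  if (length(protein) >= 2L) tab$label[protein[2L]] <- "peak2"
  ord <- order(tab$label %in% c("rayleigh_a", "second_order_b"),
               -tab$intensity)
  tab[ord, , drop = FALSE]
}

#' Track EEM peaks across an ordered set of surfaces
#'
#' Matches the non-scatter peaks of successive surfaces to those of the
#' first surface by nearest excitation line, and reports the intensity
#' and emission-position sequence of each peak (the Table-2-style
#' trajectory: progressive intensity loss with blue-shifting emission
#' indicates conformational change). A peak absent from a surface
#' yields `NA` entries and is flagged.
#'
#' @param surfaces ordered list of [eem_surface()]s.
#' @param scatter_tol passed to [find_3d_peaks()].
#' @param match_tol maximum excitation distance (nm) for matching
#'   (default 15).
#' @return A list of class `"peak_trajectory"`: one element per
#'   reference peak with `excitation`, `emission` and `intensity`
#'   sequences, plus a `missing` flag vector.
#' @export
peak_trajectory <- function(surfaces, scatter_tol = 5, match_tol = 15) {
  stopifnot(length(surfaces) >= 1L)
  all_peaks <- lapply(surfaces, find_3d_peaks, scatter_tol = scatter_tol)
  ref <- all_peaks[[1L]]
  ref <- ref[!(ref$label %in% c("rayleigh_a", "second_order_b")), ,
             drop = FALSE]
  if (!nrow(ref)) stop("no non-scatter peaks in the first surface",
                       call. = FALSE)
  traj <- lapply(seq_len(nrow(ref)), function(k) {
    ex0 <- ref$excitation[k]
    em <- int <- rep(NA_real_, length(surfaces))
    for (s in seq_along(surfaces)) {
      cand <- all_peaks[[s]]
      cand <- cand[!(cand$label %in% c("rayleigh_a", "second_order_b")), ,
                   drop = FALSE]
      if (!nrow(cand)) next
      d <- abs(cand$excitation - ex0)
      if (min(d) <= match_tol) {
        i <- which.min(d)
        em[s] <- cand$emission[i]
        int[s] <- cand$intensity[i]
      }
    }
    list(label = ref$label[k], excitation = ex0, emission = em,
         intensity = int, missing = is.na(int))
  })
  names(traj) <- ref$label
  structure(traj, class = "peak_trajectory")
}

#' @export
print.peak_trajectory <- function(x, ...) {
  for (p in x) {
    cat(sprintf("%s (ex %g nm):\n", p$label, p$excitation))
    cat("  emission :", paste(format(p$emission), collapse = " -> "), "\n")
    cat("  intensity:", paste(format(p$intensity), collapse = " -> "), "\n")
    if (any(p$missing)) cat("  missing in surface(s):",
                            paste(which(p$missing), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Mean residue ellipticity
#'
#' Converts a measured ellipticity in millidegrees to mean residue
#' ellipticity:
#' \deqn{MRE = \frac{\theta_{mdeg}}{10 \cdot n_{res} \cdot c \cdot l}}
#' with protein concentration `c` in mol/L and path length `l` in cm.
#' The default residue count 585 is that of human serum albumin.
#'
#' @param theta_mdeg ellipticity in millidegrees (vectorized).
#' @param path_cm path length in cm (> 0).
#' @param protein_conc molar protein concentration (> 0).
#' @param n_residues number of amino acid residues (default 585).
#' @return MRE in deg cm^2 dmol^-1.
#' @export
mre_convert <- function(theta_mdeg, path_cm, protein_conc,
                        n_residues = 585) {
  if (path_cm <= 0 || protein_conc <= 0 || n_residues <= 0)
    stop("path length, concentration and residue count must be positive",
         call. = FALSE)
  theta_mdeg / (10 * n_residues * protein_conc * path_cm)
}

#' Thermal denaturation / renaturation analysis
#'
#' Locates the unfolding onset on the forward (heating) scan and
#' quantifies how much of the native signal is regained after cooling.
#' The onset is the first temperature at which the signal leaves the
#' pre-transition baseline band (3 x SD of the signal inside
#' `baseline_window`, with a floor of 1 percent of the total signal
#' range so that noise-free curves are handled sensibly). The recovery
#' is the reverse-scan signal at the evaluation temperature as a
#' percentage of the forward-scan signal there.
#'
#' @param forward forward (heating) [melt_curve()].
#' @param reverse reverse (cooling) [melt_curve()].
#' @param baseline_window temperature window (degrees C) treated as
#'   pre-transition baseline; default `c(25, 40)`.
#' @param eval_temperature temperature at which recovery is evaluated;
#'   default the shared start (lowest) temperature.
#' @return An object of class `"melt_analysis"` with `onset_T`,
#'   `transition_range` (temperatures at 5 and 95 percent of the total
#'   signal change), `signal_at_start`, `signal_at_end`,
#'   `recovery_percent` and flags.
#' @export
melt_analysis <- function(forward, reverse,
                          baseline_window = c(25, 40),
                          eval_temperature = NULL) {
  stopifnot(inherits(forward, "melt_curve"),
            inherits(reverse, "melt_curve"))
  lo_f <- min(forward$temperature); lo_r <- min(reverse$temperature)
  if (max(forward$temperature) < lo_r ||
      max(reverse$temperature) < lo_f)
    stop("forward and reverse curves do not overlap in temperature",
         call. = FALSE)
  if (abs(lo_f - lo_r) > 1e-6)
    warning("forward and reverse scans start at different temperatures")
  if (is.null(eval_temperature)) eval_temperature <- max(lo_f, lo_r)

  tw <- forward$temperature >= baseline_window[1L] &
        forward$temperature <= baseline_window[2L]
  if (sum(tw) < 2L)
    stop("baseline window contains fewer than 2 forward-scan points",
         call. = FALSE)
  base_mean <- mean(forward$mre[tw])
  base_sd <- stats::sd(forward$mre[tw])
  total_range <- diff(range(forward$mre))
  threshold <- max(3 * base_sd, 0.01 * total_range)

  dev <- abs(forward$mre - base_mean)
  beyond <- which(dev > threshold & forward$temperature >
                    baseline_window[2L])
  onset <- if (length(beyond)) forward$temperature[beyond[1L]] else NA_real_
  flat <- is.na(onset)
  if (flat) warning("no unfolding transition detected; onset undefined")

  s_start <- forward$mre[1L]
  s_end <- forward$mre[length(forward$mre)]
  frac <- (forward$mre - base_mean) / (s_end - base_mean)
  t_range <- if (!flat) {
    t05 <- forward$temperature[which(frac >= 0.05)[1L]]
    t95 <- forward$temperature[which(frac >= 0.95)[1L]]
    c(t05, t95)
  } else c(NA_real_, NA_real_)

  f_at <- stats::approx(forward$temperature, forward$mre,
                        xout = eval_temperature, rule = 1)$y
  r_at <- stats::approx(reverse$temperature, reverse$mre,
                        xout = eval_temperature, rule = 1)$y
  if (is.na(f_at) || is.na(r_at))
    stop("evaluation temperature outside a scan's range", call. = FALSE)
  recovery <- 100 * r_at / f_at
  structure(list(onset_T = onset, transition_range = t_range,
                 signal_at_start = s_start, signal_at_end = s_end,
                 recovery_percent = recovery,
                 eval_temperature = eval_temperature,
                 baseline_mean = base_mean, threshold = threshold,
                 no_transition = flat,
                 recovery_flag = recovery > 110),
            class = "melt_analysis")
}

#' @export
print.melt_analysis <- function(x, ...) {
  cat("Thermal melt analysis\n")
  if (x$no_transition) cat("  no transition detected\n")
  else {
    cat(sprintf("  onset: %.1f degC; transition %.1f-%.1f degC\n",
                x$onset_T, x$transition_range[1L], x$transition_range[2L]))
  }
  cat(sprintf("  recovery at %.1f degC: %.1f%%%s\n", x$eval_temperature,
              x$recovery_percent,
              if (isTRUE(x$recovery_flag)) " (> 110%: check data)" else ""))
  invisible(x)
}
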