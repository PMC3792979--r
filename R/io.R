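# CSV readers/writers for the package's long-format schemas.
#
# Titration CSV (one row per wavelength per titration point):
#   series_id, kind, temperature_C, protein_conc_M, ligand_conc_M,
#   wavelength_nm, value [, A_ex, A_em]
# EEM CSV:  excitation_nm, emission_nm, value
# Melt CSV: direction, temperature_C, mre222

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' Read titration series from a long-format CSV
#'
#' Rows are grouped by `(series_id, temperature_C)`; each group becomes
#' one [titration_series()]. Within a group, rows sharing a
#' `ligand_conc_M` value form one spectrum (ordered by wavelength in the
#' file). Optional columns `A_ex`/`A_em` carry per-point absorbance
#' increments, repeated on every row of the point.
#'
#' @param path path to a CSV file.
#' @return A single [titration_series()] if the file holds one series,
#'   otherwise a named list of series (names `"<series_id>@<T>"`).
#' @export
read_titration <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("series_id", "kind", "temperature_C",
                        "protein_conc_M", "ligand_conc_M",
                        "wavelength_nm", "value"), path)
  has_abs <- all(c("A_ex", "A_em") %in% names(df))
  groups <- split(df, list(df$series_id, df$temperature_C), drop = TRUE)
  out <- lapply(groups, function(g) {
    concs <- sort(unique(g$ligand_conc_M))
    spectra <- vector("list", length(concs))
    abs_tab <- if (has_abs) data.frame(A_ex = numeric(length(concs)),
                                       A_em = numeric(length(concs)))
    for (i in seq_along(concs)) {
      rows <- g[g$ligand_conc_M == concs[i], ]
      kind <- rows$kind[1L]
      meta <- list()
      if ("delta_lambda" %in% names(rows)) meta$delta_lambda <-
          rows$delta_lambda[1L]
      spectra[[i]] <- tryCatch(
        spectrum(rows$wavelength_nm, rows$value, kind = kind, meta = meta),
        error = function(e) stop(sprintf(
          "%s: series '%s', ligand_conc_M = %g: %s",
          path, g$series_id[1L], concs[i], conditionMessage(e)),
          call. = FALSE))
      if (has_abs) {
        abs_tab$A_ex[i] <- rows$A_ex[1L]
        abs_tab$A_em[i] <- rows$A_em[1L]
      }
    }
    titration_series(protein_conc = g$protein_conc_M[1L],
                     ligand_conc = concs,
                     temperature = g$temperature_C[1L],
                     spectra = spectra,
                     absorbance = abs_tab)
  })
  names(out) <- vapply(groups, function(g)
    sprintf("%s@%g", g$series_id[1L], g$temperature_C[1L]), character(1L))
  if (length(out) == 1L) out[[1L]] else out
}

#' Write titration series to a long-format CSV
#'
#' Inverse of [read_titration()]; the round trip is lossless to numerical
#' precision. Non-finite signal values are rejected.
#'
#' @param series a [titration_series()] or a (named) list of them.
#' @param path output CSV path.
#' @param series_id identifier written to the `series_id` column (recycled
#'   over a list of series).
#' @export
write_titration <- function(series, path, series_id = "series1") {
  if (inherits(series, "titration_series")) series <- list(series)
  series_id <- rep_len(series_id, length(series))
  rows <- lapply(seq_along(series), function(k) {
    s <- series[[k]]
    do.call(rbind, lapply(seq_along(s$ligand_conc), function(i) {
      sp <- s$spectra[[i]]
      stop_if_not_finite(sp$value, sprintf("spectrum %d of series %d", i, k))
      d <- data.frame(series_id = series_id[k], kind = sp$kind,
                      temperature_C = s$temperature,
                      protein_conc_M = s$protein_conc,
                      ligand_conc_M = s$ligand_conc[i],
                      wavelength_nm = sp$wavelength, value = sp$value)
      if (!is.null(s$absorbance)) {
        d$A_ex <- s$absorbance$A_ex[i]
        d$A_em <- s$absorbance$A_em[i]
      }
      d
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a single spectrum from a two-column CSV
#'
#' Expects columns `wavelength_nm` and `value`.
#'
#' @param path CSV path.
#' @inheritParams spectrum
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, kind = "emission", meta = list()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("wavelength_nm", "value"), path)
  spectrum(df$wavelength_nm, df$value, kind = kind, meta = meta)
}

#' Write a spectrum to a two-column CSV
#' @param spectrum a [spectrum()].
#' @param path output CSV path.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "spectrum"))
  stop_if_not_finite(spectrum$value, "spectrum values")
  utils::write.csv(data.frame(wavelength_nm = spectrum$wavelength,
                              value = spectrum$value),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an excitation-emission matrix from CSV
#'
#' Expects columns `excitation_nm`, `emission_nm`, `value`, one row per
#' grid cell (full grid required).
#'
#' @param path CSV path.
#' @return An [eem_surface()].
#' @export
read_eem <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("excitation_nm", "emission_nm", "value"), path)
  ex <- sort(unique(df$excitation_nm))
  em <- sort(unique(df$emission_nm))
  if (nrow(df) != length(ex) * length(em))
    stop(sprintf("%s: expected a full %d x %d grid, got %d rows",
                 path, length(ex), length(em), nrow(df)), call. = FALSE)
  m <- matrix(NA_real_, length(ex), length(em))
  m[cbind(match(df$excitation_nm, ex), match(df$emission_nm, em))] <- df$value
  eem_surface(ex, em, m)
}

#' Write an excitation-emission matrix to CSV
#' @param surface an [eem_surface()].
#' @param path output CSV path.
#' @export
write_eem <- function(surface, path) {
  stopifnot(inherits(surface, "eem_surface"))
  stop_if_not_finite(surface$intensity, "EEM intensities")
  grid <- expand.grid(excitation_nm = surface$excitation,
                      emission_nm = surface$emission)
  grid$value <- as.vector(surface$intensity)  # column-major matches expand.grid
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' Read melt curves from CSV
#'
#' Expects columns `direction`, `temperature_C`, `mre222`; returns a list
#' with `forward` and/or `reverse` [melt_curve()]s.
#'
#' @param path CSV path.
#' @export
read_melt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("direction", "temperature_C", "mre222"), path)
  out <- lapply(split(df, df$direction), function(g)
    melt_curve(g$temperature_C, g$mre222, direction = g$direction[1L]))
  out
}

#' Write melt curves to CSV
#' @param curves a [melt_curve()] or list of them.
#' @param path output CSV path.
#' @export
write_melt <- function(curves, path) {
  if (inherits(curves, "melt_curve")) curves <- list(curves)
  rows <- do.call(rbind, lapply(curves, function(cv) {
    stop_if_not_finite(cv$mre, "melt signal")
    data.frame(direction = cv$direction, temperature_C = cv$temperature,
               mre222 = cv$mre)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
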