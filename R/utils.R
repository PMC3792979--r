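# internal helpers shared across modules

# trapezoidal integral on an irregular grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}

check_strictly_increasing <- function(x, what) {
  if (any(diff(x) <= 0))
    stop(sprintf("%s must be strictly increasing (violation at position %d)",
                 what, which(diff(x) <= 0)[1L] + 1L), call. = FALSE)
  invisible(x)
}

# union of two wavelength grids restricted to their common support
union_grid <- function(x1, x2) {
  lo <- max(min(x1), min(x2))
  hi <- min(max(x1), max(x2))
  if (lo >= hi) return(numeric(0))
  sort(unique(c(x1[x1 >= lo & x1 <= hi], x2[x2 >= lo & x2 <= hi], lo, hi)))
}

fmt_sci <- function(x, digits = 3) formatC(x, format = "e", digits = digits)
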