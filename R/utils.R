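#' @keywords internal
"_PACKAGE"

# grams of carbon per mole
C_MOLAR_MASS <- 12.011

# mean Earth radius (m), spherical approximation used for pixel areas
EARTH_RADIUS_M <- 6371000

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Trapezoidal integral of y(x)
#'
#' Thin wrapper over [pracma::trapz()] that tolerates length-1 input.
#' @param x,y numeric vectors of equal length, `x` increasing.
#' @return scalar integral.
#' @keywords internal
trapz_int <- function(x, y) {
  if (length(x) < 2L) return(0)
  pracma::trapz(x, y)
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(unlist(x)))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Convert a calendar date to decimal year
#' @param year,doy integer year and day of year.
#' @keywords internal
decimal_year <- function(year, doy) year + (doy - 0.5) / 365
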