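#' Wavenumber axis for the high-wavenumber CARS window
#'
#' Validates a vector of Raman shifts (cm^-1). The acquisition window is
#' 2700--3200 cm^-1; the axis must be strictly increasing with at least two
#' points.
#'
#' @param values numeric vector of Raman shifts in cm^-1.
#' @return the validated numeric vector with class `"WavenumberAxis"`.
#' @examples
#' ax <- wavenumber_axis(seq(2700, 3200, by = 50))
#' @export
wavenumber_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("axis needs at least 2 wavenumbers")
  if (any(diff(values) <= 0)) stop("axis must be strictly increasing")
  if (any(values < 2700 | values > 3200))
    stop("wavenumbers must lie within [2700, 3200] cm^-1")
  structure(values, class = "WavenumberAxis")
}

#' Default acquisition axis
#'
#' @param step sampling step in cm^-1 (default 10).
#' @return a [wavenumber_axis()] spanning 2700--3200 cm^-1.
#' @export
default_axis <- function(step = 10) wavenumber_axis(seq(2700, 3200, by = step))

#' Index of the axis point nearest a wavenumber
#'
#' @param axis a [wavenumber_axis()] (or plain numeric vector).
#' @param wn target wavenumber in cm^-1.
#' @return integer index into `axis`.
#' @export
nearest_index <- function(axis, wn) which.min(abs(as.numeric(axis) - wn))
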