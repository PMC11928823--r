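# Unit handling. Everything inside the package is strict SI (m, N, Pa, s, V,
# rad); conversion happens once, at the I/O boundary, driven by the unit
# declared for each column in the column map.

#' Convert a numeric vector to SI base units
#'
#' Supported units: time (s, ms, min), length (m, mm, um, nm), force (N, mN,
#' uN, nN), stress (Pa, kPa, MPa, GPa), voltage (V, mV), angle (rad, mrad),
#' and dimensionless (`""`, `"1"`, `"-"`, `"percent"`/`"%"`).
#'
#' @param x Numeric vector.
#' @param unit Unit string as declared in a column map.
#' @return `x` expressed in the SI base unit of its quantity.
#' @examples
#' to_si(c(1, 2), "mN") # newtons
#' to_si(5, "mm")       # metres
#' @export
to_si <- function(x, unit) {
  factor <- si_factor(unit)
  x * factor
}

si_factor <- function(unit) {
  unit <- trimws(as.character(unit %||% ""))
  # "um"/"uN" accepted as ASCII spellings of micro-units
  table <- c(
    s = 1, ms = 1e-3, min = 60,
    m = 1, mm = 1e-3, um = 1e-6, "µm" = 1e-6, nm = 1e-9,
    N = 1, mN = 1e-3, uN = 1e-6, "µN" = 1e-6, nN = 1e-9,
    Pa = 1, kPa = 1e3, MPa = 1e6, GPa = 1e9,
    V = 1, mV = 1e-3,
    rad = 1, mrad = 1e-3
  )
  if (unit %in% c("", "1", "-", "dimensionless")) return(1)
  if (unit %in% c("percent", "%")) return(1e-2)
  if (!unit %in% names(table)) {
    stop_format(sprintf("unknown unit '%s'", unit))
  }
  unname(table[[unit]])
}
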