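#' Convert between the package's working units and SI
#'
#' User-facing quantities are expressed in micrometres and minutes (the
#' natural scales of a ~100 um crystal observed over hours), while diffusion
#' coefficients are reported in SI (m^2/s). Every unit conversion in the
#' package is routed through this single function so that the mapping can be
#' audited in one place.
#'
#' @param x numeric vector to convert.
#' @param from,to unit names. Supported: `"um"`, `"m"`, `"nm"` (length);
#'   `"s"`, `"min"`, `"hr"` (time); `"um2/s"`, `"m2/s"` (diffusivity).
#' @return `x` expressed in the `to` unit.
#' @examples
#' convert_unit(1.5e-15, "m2/s", "um2/s")  # 1.5e-3 um^2/s
#' convert_unit(1500, "min", "s")
#' @export
convert_unit <- function(x, from, to) {
  tbl <- c(
    "um" = 1e-6, "m" = 1, "nm" = 1e-9,          # -> metres
    "s" = 1, "min" = 60, "hr" = 3600,           # -> seconds
    "um2/s" = 1e-12, "m2/s" = 1                 # -> m^2/s
  )
  dims <- c(
    "um" = "length", "m" = "length", "nm" = "length",
    "s" = "time", "min" = "time", "hr" = "time",
    "um2/s" = "diffusivity", "m2/s" = "diffusivity"
  )
  if (!from %in% names(tbl)) stop("unknown unit: ", from)
  if (!to %in% names(tbl)) stop("unknown unit: ", to)
  if (dims[[from]] != dims[[to]])
    stop("incompatible units: ", from, " -> ", to)
  x * tbl[[from]] / tbl[[to]]
}
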