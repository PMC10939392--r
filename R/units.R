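#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Mass prefixes expressed in Gg (1 Gg = 1e9 g = 1e6 kg = 1e3 t; kt == Gg).
.mass_in_gg <- c(
  g = 1e-9, kg = 1e-6, t = 1e-3, Mg = 1e-3, kt = 1, Gg = 1, Tg = 1e3
)

# Units whose "amount" is not a mass; scale is 1 in their own unit.
.count_units <- c("TJ", "person", "head")

#' Parse an amount unit such as "Gg N", "t product" or "TJ"
#'
#' An amount unit is either a bare count unit (`TJ`, `person`, `head`) or a
#' mass prefix followed by a substance tag (`N`, `N2O`, `N2O-N`, `product`,
#' `dm`, `fuel`, ...). Returns a list with the scale in Gg (or 1 for count
#' units) and the substance string.
#' @keywords internal
parse_amount_unit <- function(unit) {
  unit <- trimws(unit)
  if (unit %in% .count_units) {
    return(list(scale = 1, substance = unit, mass = FALSE))
  }
  parts <- strsplit(unit, "\\s+")[[1]]
  if (length(parts) != 2L || !parts[1] %in% names(.mass_in_gg)) {
    abort(paste0(
      "Unrecognized amount unit '", unit, "'. Expected '<",
      paste(names(.mass_in_gg), collapse = "|"),
      "> <substance>' or one of: ", paste(.count_units, collapse = ", "), "."
    ), class = "n2o_unit_error")
  }
  list(scale = unname(.mass_in_gg[parts[1]]), substance = parts[2], mass = TRUE)
}

#' Parse an emission-factor unit such as "kg N2O-N/kg N"
#'
#' EF units are written `<emitted amount>/<activity amount>`, e.g.
#' `"kg N2O-N/kg N"`, `"t N2O/t product"`, `"kg N2O/TJ"`. The numerator
#' substance must be `N2O` or `N2O-N`.
#' @keywords internal
parse_ef_unit <- function(unit) {
  sides <- strsplit(unit, "/", fixed = TRUE)[[1]]
  if (length(sides) != 2L) {
    abort(paste0("EF unit '", unit, "' must have the form '<emitted>/<activity>'."),
          class = "n2o_unit_error")
  }
  num <- parse_amount_unit(sides[1])
  den <- parse_amount_unit(sides[2])
  if (!num$substance %in% c("N2O", "N2O-N")) {
    abort(paste0("EF numerator in '", unit, "' must be an N2O or N2O-N mass."),
          class = "n2o_unit_error")
  }
  list(num = num, den = den)
}

#' Convert a mass of N2O-N to a mass of N2O
#'
#' Emission factors for soil and manure pathways are expressed on the
#' nitrogen basis (N2O-N); reported emissions use the full molecule. The
#' conversion is the molar-mass ratio 44/28.
#'
#' @param mass_n2o_n Non-negative mass on the N2O-N basis (any mass unit).
#' @return The same mass on the N2O basis (`mass * 44 / 28`).
#' @seealso [n2o_to_n2o_n()] for the inverse.
#' @examples
#' n2o_n_to_n2o(28) # 44
#' @export
n2o_n_to_n2o <- function(mass_n2o_n) {
  if (any(mass_n2o_n < 0, na.rm = TRUE)) {
    abort("N2O-N mass must be non-negative.", class = "n2o_domain_error")
  }
  mass_n2o_n * 44 / 28
}

#' Convert a mass of N2O to a mass of N2O-N
#' @param mass_n2o Non-negative mass of N2O.
#' @return `mass * 28 / 44`.
#' @export
n2o_to_n2o_n <- function(mass_n2o) {
  if (any(mass_n2o < 0, na.rm = TRUE)) {
    abort("N2O mass must be non-negative.", class = "n2o_domain_error")
  }
  mass_n2o * 28 / 44
}
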