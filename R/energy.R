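#' Fuel-combustion N2O emissions
#'
#' Stationary and mobile combustion: activity is either an energy amount in
#' TJ or a fuel mass with a net calorific value (NCV, TJ per t), and the EF
#' is on a per-TJ basis. The eleven energy categories of the inventory are a
#' closed set (see [fan_categories()]), so the sector subtotal is
#' well-defined.
#'
#' @param quantity Fuel quantity, non-negative.
#' @param unit `"TJ"` or a fuel mass unit (`"t fuel"`, `"kt fuel"`, ...).
#' @param ef EF in kg N2O per TJ.
#' @param ncv Net calorific value in TJ per t of fuel; required for
#'   mass-based activity.
#' @return Emission in Gg N2O-N.
#' @examples
#' combustion_emission(1000, "TJ", 1.5)  # 1.5 t N2O on the N2O basis
#' @export
combustion_emission <- function(quantity, unit, ef, ncv = NULL) {
  if (any(quantity < 0)) {
    abort("Fuel quantity must be non-negative.", class = "n2o_domain_error")
  }
  u <- parse_amount_unit(unit)
  if (u$substance == "TJ") {
    tj <- quantity
  } else {
    if (is.null(ncv) || any(is.na(ncv))) {
      abort(paste0("Mass-based fuel activity ('", unit,
                   "') requires a net calorific value (TJ per t)."),
            class = "n2o_config_error")
    }
    if (any(ncv <= 0)) {
      abort("Net calorific value must be positive.",
            class = "n2o_domain_error")
    }
    tonnes <- quantity * u$scale / .mass_in_gg[["t"]]
    tj <- tonnes * ncv
  }
  emission(tj, "TJ", ef, "kg N2O/TJ")
}

#' Fugitive N2O emissions from fuels
#'
#' Plain activity x EF in the activity's native units; kept as its own
#' operation because fugitive activity is not an energy amount.
#'
#' @param quantity Activity amount, non-negative.
#' @param unit Activity unit (any registered amount unit).
#' @param ef EF value.
#' @param ef_unit EF unit composing with `unit`, e.g. `"kg N2O/kt fuel"`.
#' @return Emission in Gg N2O-N.
#' @export
fugitive_emission <- function(quantity, unit, ef, ef_unit) {
  emission(quantity, unit, ef, ef_unit)
}
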