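#' Wastewater treatment and discharge N2O
#'
#' Protein-based nitrogen load: `N = population * protein * 0.16 *
#' mult_nonconsumed * mult_industrial - sludge N`, floored at zero (with a
#' warning when the floor binds), then `emission = N * EF`.
#'
#' @param population Persons (non-negative).
#' @param protein_kg Protein intake, kg per person per year.
#' @param frac_npr N content of protein (kg N per kg protein, default 0.16).
#' @param mult_nonconsumed,mult_industrial Load multipliers for
#'   non-consumed protein and industrial co-discharge (default 1).
#' @param sludge_n_gg N removed with sludge (Gg N).
#' @param ef Effluent EF, kg N2O-N per kg N (default 0.005; its literature
#'   uncertainty is large, propagated in the uncertainty module).
#' @return Emission in Gg N2O-N.
#' @examples
#' wastewater_emission(1e6, 30, ef = 0.005) # 0.024 Gg N2O-N
#' @export
wastewater_emission <- function(population, protein_kg, frac_npr = 0.16,
                                mult_nonconsumed = 1, mult_industrial = 1,
                                sludge_n_gg = 0, ef = 0.005) {
  if (any(population < 0) || any(protein_kg < 0) || any(frac_npr < 0) ||
      any(mult_nonconsumed < 0) || any(mult_industrial < 0)) {
    abort("Wastewater inputs must be non-negative.",
          class = "n2o_domain_error")
  }
  gross_gg <- population * protein_kg * frac_npr *
    mult_nonconsumed * mult_industrial / 1e6
  n_load <- gross_gg - sludge_n_gg
  if (any(n_load < 0)) {
    warn("Sludge N exceeds the gross N load; load floored at 0.")
    n_load <- pmax(n_load, 0)
  }
  emission(n_load, "Gg N", ef, "kg N2O-N/kg N")
}

#' Solid-waste composting and incineration N2O
#'
#' `composted * EF_compost + incinerated * EF_incin` with per-mass EFs.
#'
#' @param compost_kt,incin_kt Treated masses (kt), non-negative.
#' @param ef_compost,ef_incin EFs in kg N2O per t treated.
#' @return Emission in Gg N2O-N.
#' @export
solid_waste_emission <- function(compost_kt, incin_kt,
                                 ef_compost = 0.6, ef_incin = 0.05) {
  if (any(compost_kt < 0) || any(incin_kt < 0)) {
    abort("Treated masses must be non-negative.", class = "n2o_domain_error")
  }
  emission(compost_kt, "kt waste", ef_compost, "kg N2O/t waste") +
    emission(incin_kt, "kt waste", ef_incin, "kg N2O/t waste")
}
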