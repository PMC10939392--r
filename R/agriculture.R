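#' Default agricultural emission-factor set
#'
#' Bundles the parameters of the cropland/livestock pathways:
#' \describe{
#'   \item{ef1}{Direct soil EF by climate region and land type
#'     (kg N2O-N per kg N). Regional upland values are high in the East
#'     (0.0157) and Northeast (0.0149) and lower elsewhere; paddy values
#'     span 0.0052-0.0161. Missing strata fall back to the land-type
#'     defaults of the IPCC 2019 refinement (0.01 upland, 0.004 paddy).}
#'   \item{ef3_mms}{Manure-management EF by system (kg N2O-N per kg N).}
#'   \item{ef3_pasture}{Pasture-deposition EF by species group: 0.004 for
#'     cows/swine/poultry, 0.003 for sheep/goat/other (IPCC 2019 values).}
#'   \item{ef4, ef5}{Indirect EFs: volatilization-redeposition (0.01) and
#'     leaching/runoff (0.0065 kg N2O-N per kg N leached).}
#'   \item{frac_gasf, frac_gasm}{Volatilized fractions of synthetic and
#'     organic N (0.11, 0.21).}
#'   \item{frac_leach}{Default leached fraction by land type; provincial
#'     values in data may range 0.0121-0.0827 (paddy) and 0.0061-0.0874
#'     (upland).}
#'   \item{burning_cf, burning_ef}{Residue combustion factor (0.8) and
#'     burning EF (0.07 kg N2O per t dry matter burned).}
#' }
#' All values are editable configuration; tests pass parameters explicitly.
#'
#' @return A list of parameter tables and scalars.
#' @export
ag_ef_defaults <- function() {
  ef1 <- tibble(
    climate_region = rep(c("East", "Northeast", "North", "Central",
                           "Southwest", "Northwest"), each = 2),
    land_type = rep(c("upland", "paddy"), times = 6),
    value = c(0.0157, 0.0161,
              0.0149, 0.0120,
              0.0093, 0.0060,
              0.0085, 0.0100,
              0.0075, 0.0080,
              0.0065, 0.0052)
  )
  list(
    ef1 = ef1,
    ef1_default = c(upland = 0.01, paddy = 0.004),
    ef3_mms = c(lagoon = 0.0, liquid = 0.005, solid = 0.01,
                drylot = 0.02, other = 0.005),
    ef3_pasture = c(cattle = 0.004, cows = 0.004, swine = 0.004,
                    poultry = 0.004, sheep = 0.003, goat = 0.003,
                    other = 0.003),
    ef4 = 0.01,
    ef5 = 0.0065,
    frac_gasf = 0.11,
    frac_gasm = 0.21,
    frac_leach = c(upland = 0.04, paddy = 0.05),
    burning_cf = 0.8,
    burning_ef = 0.07
  )
}

#' @keywords internal
ef1_for <- function(efs, climate_region, land_type) {
  hit <- efs$ef1[efs$ef1$climate_region == climate_region &
                 efs$ef1$land_type == land_type, ]
  if (nrow(hit) == 1L) return(hit$value)
  if (!land_type %in% names(efs$ef1_default)) {
    abort(paste0("Unknown land type '", land_type, "'."),
          class = "n2o_lookup_error")
  }
  unname(efs$ef1_default[land_type])
}

#' Direct soil emissions from nitrogen inputs to cropland
#'
#' Each N-input component (synthetic fertilizer, applied manure, crop
#' residue, mineralized soil N, deposited N reaching cropland) is multiplied
#' by the direct soil EF1 for the province's climate region and land type.
#' The five components are returned as separate sub-sources so the inventory
#' rows remain recoverable.
#'
#' @param bundle One-row list/tibble with `year`, `province`, `land_type`
#'   and Gg N components `f_sn`, `f_on`, `f_cr`, `f_som`, `f_dep`
#'   (missing components count as 0).
#' @param efs EF set, see [ag_ef_defaults()].
#' @param registry Region registry for climate-region resolution
#'   (defaults to [region_registry()]).
#' @return Emission-estimate tibble with categories `fertilizer_cropland`,
#'   `manure_application`, `crop_residue`, `n_mineralization`,
#'   `n_deposition`.
#' @export
direct_soil <- function(bundle, efs = ag_ef_defaults(), registry = NULL) {
  if (is.null(registry)) registry <- region_registry()
  cz <- registry$climate_region[registry$province == bundle$province]
  if (length(cz) != 1L) {
    abort(paste0("Province '", bundle$province,
                 "' has no climate-region assignment."),
          class = "n2o_lookup_error")
  }
  ef1 <- ef1_for(efs, cz, bundle$land_type)
  comp <- c(fertilizer_cropland = "f_sn", manure_application = "f_on",
            crop_residue = "f_cr", n_mineralization = "f_som",
            n_deposition = "f_dep")
  vals <- vapply(comp, function(f) {
    v <- bundle[[f]]
    if (is.null(v) || is.na(v)) 0 else as.numeric(v)
  }, numeric(1))
  if (any(vals < 0)) {
    abort("N-input components must be non-negative.",
          class = "n2o_domain_error")
  }
  emission_estimate(
    year = bundle$year, province = bundle$province, sector = "agriculture",
    category = names(comp),
    n2o_n_gg = unname(emission(vals, "Gg N", ef1, "kg N2O-N/kg N"))
  )
}

#' Indirect emissions from nitrogen leaching and runoff
#'
#' The fraction of applied N lost by leaching/runoff enters water systems
#' where a share is reduced to N2O: `N * frac_leach * EF5`.
#'
#' @param n_applied Applied N (Gg N).
#' @param frac_leach Leached fraction, in `[0, 1]`.
#' @param ef5 Leaching/runoff EF (kg N2O-N per kg N leached), default 0.0065.
#' @return Emission in Gg N2O-N.
#' @export
indirect_leaching <- function(n_applied, frac_leach, ef5 = 0.0065) {
  if (any(frac_leach < 0 | frac_leach > 1)) {
    abort("frac_leach must lie in [0, 1].", class = "n2o_domain_error")
  }
  emission(n_applied * frac_leach, "Gg N", ef5, "kg N2O-N/kg N")
}

#' Indirect emissions from volatilization and redeposition
#'
#' Ammonia/NOx volatilized from synthetic (`frac_gasf`) and organic
#' (`frac_gasm`) N redeposits on soils where EF4 applies:
#' `(syn * frac_gasf + org * frac_gasm) * EF4`.
#'
#' @param n_syn,n_org Synthetic and organic N applied (Gg N).
#' @param frac_gasf,frac_gasm Volatilized fractions in `[0, 1]`.
#' @param ef4 Redeposition EF (kg N2O-N per kg N volatilized).
#' @return Emission in Gg N2O-N.
#' @export
indirect_deposition <- function(n_syn, n_org, frac_gasf = 0.11,
                                frac_gasm = 0.21, ef4 = 0.01) {
  if (any(c(frac_gasf, frac_gasm) < 0 | c(frac_gasf, frac_gasm) > 1)) {
    abort("Volatilized fractions must lie in [0, 1].",
          class = "n2o_domain_error")
  }
  emission(n_syn * frac_gasf + n_org * frac_gasm, "Gg N", ef4,
           "kg N2O-N/kg N")
}

#' Manure excretion and management-system emissions
#'
#' Excreted N follows the livestock mass basis:
#' `N_ex = headcount * (mass/1000) * rate * 365` with the excretion rate in
#' kg N per 1000 kg animal mass per day. Manure is routed by the management
#' fractions; managed systems emit `N_ex * frac(system) * EF3(system)`,
#' while N routed to pasture and to soil application is returned for the
#' downstream pasture/application pathways (not emitted here, so nothing is
#' double counted).
#'
#' @param rec One-row list/tibble with `headcount`, `mass_kg`,
#'   `excretion_rate`, `frac_pasture`, `frac_applied` and named managed
#'   fractions `frac_mms_<system>` matching `names(efs$ef3_mms)`.
#' @param efs EF set ([ag_ef_defaults()]).
#' @return List with `n_ex_gg`, `mms` (tibble system/emission Gg N2O-N),
#'   `n_pasture_gg`, `n_applied_gg`, `n2o_n_gg` (managed-system total).
#' @export
manure_management <- function(rec, efs = ag_ef_defaults()) {
  if (rec$headcount < 0) {
    abort("Headcount must be non-negative.", class = "n2o_domain_error")
  }
  mms_cols <- grep("^frac_mms_", names(rec), value = TRUE)
  fracs <- c(rec$frac_pasture, rec$frac_applied,
             vapply(mms_cols, function(f) as.numeric(rec[[f]]), numeric(1)))
  if (any(fracs < 0 | fracs > 1) || abs(sum(fracs) - 1) > 1e-9) {
    abort("Manure management fractions must lie in [0,1] and sum to 1.",
          class = "n2o_consistency_error")
  }
  n_ex <- rec$headcount * (rec$mass_kg / 1000) * rec$excretion_rate * 365 / 1e6
  systems <- sub("^frac_mms_", "", mms_cols)
  unknown <- setdiff(systems, names(efs$ef3_mms))
  if (length(unknown) > 0) {
    abort(paste0("No EF3 for management system(s): ",
                 paste(unknown, collapse = ", ")), class = "n2o_lookup_error")
  }
  sys_frac <- vapply(mms_cols, function(f) as.numeric(rec[[f]]), numeric(1))
  mms <- tibble(
    system = systems,
    n_gg = n_ex * sys_frac,
    n2o_n_gg = n_ex * sys_frac * unname(efs$ef3_mms[systems])
  )
  list(
    n_ex_gg = n_ex,
    mms = mms,
    n_pasture_gg = n_ex * rec$frac_pasture,
    n_applied_gg = n_ex * rec$frac_applied,
    n2o_n_gg = sum(mms$n2o_n_gg)
  )
}

#' Emissions from manure deposited on pasture
#'
#' @param n_deposited N excreted on pasture (Gg N).
#' @param species Species/group name resolvable in `efs$ef3_pasture`
#'   (0.004 for cows/swine/poultry, 0.003 for sheep/goat/other).
#' @param efs EF set.
#' @return Emission in Gg N2O-N.
#' @export
manure_pasture <- function(n_deposited, species, efs = ag_ef_defaults()) {
  if (!species %in% names(efs$ef3_pasture)) {
    abort(paste0("No pasture EF3 for species group '", species, "'."),
          class = "n2o_lookup_error")
  }
  emission(n_deposited, "Gg N", unname(efs$ef3_pasture[species]),
           "kg N2O-N/kg N")
}

#' Emissions from crop-residue burning
#'
#' `residue mass * combustion factor * EF` with the EF on a per-tonne
#' dry-matter basis; returned on the internal N2O-N basis.
#'
#' @param residue_gg_dm Residue mass (Gg dry matter).
#' @param combustion_factor Fraction actually combusted, in `[0, 1]`.
#' @param ef_burn EF in kg N2O per t dry matter burned.
#' @return Emission in Gg N2O-N.
#' @export
biomass_burning <- function(residue_gg_dm, combustion_factor, ef_burn = 0.07) {
  if (any(combustion_factor < 0 | combustion_factor > 1)) {
    abort("Combustion factor must lie in [0, 1].", class = "n2o_domain_error")
  }
  emission(residue_gg_dm * combustion_factor, "Gg dm", ef_burn, "kg N2O/t dm")
}
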