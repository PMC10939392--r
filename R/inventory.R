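#' Default sector EF configuration for the full inventory run
#'
#' Per-TJ combustion EFs by energy category, industrial per-tonne EFs,
#' waste EFs, and the uncertainty tags (distribution + CV) attached to the
#' activity data and EFs of each sector. Values are IPCC-default-style
#' placeholders, editable by the caller; the agricultural set comes from
#' [ag_ef_defaults()].
#'
#' @return List with `energy_ef` (named, kg N2O/TJ), `fugitive_ef`
#'   (kg N2O/kt fuel), `industry_ef` (kg N2O/t product), waste EFs, and
#'   `uncertainty` (tibble sector/ad_cv/ef_dist/ef_cv).
#' @export
inventory_ef_defaults <- function() {
  list(
    energy_ef = c(
      electricity_generation = 2.4, heat_plants = 1.5,
      petroleum_refining = 0.6, solid_fuel_manufacture = 1.5,
      other_energy_industries = 1.5, manufacturing_construction = 1.5,
      transport = 2.9, residential = 1.5,
      agriculture_forestry_fishing = 1.5, non_specified = 1.5
    ),
    fugitive_ef = 0.5,                          # kg N2O per kt fuel
    industry_ef = c(adipic = 300, nitric = 9),  # kg N2O per t product
    wastewater_ef = 0.005,                      # kg N2O-N per kg N
    compost_ef = 0.6, incin_ef = 0.05,          # kg N2O per t
    uncertainty = tibble(
      sector = c("agriculture", "energy", "industry", "waste"),
      ad_cv = c(0.10, 0.08, 0.15, 0.08),
      ef_dist = "lognormal",
      ef_cv = c(0.30, 0.25, 0.20, 1.00)
    )
  )
}

#' Run the full anthropogenic inventory on an activity bundle
#'
#' Applies every sector engine to the activity tables (typically from
#' [generate_activity()]) and returns the long province-level
#' emission-estimate table with uncertainty tags ready for [propagate()].
#' Category paths:
#' agriculture — direct soil EF1 on each N input (fertilizer, applied
#' manure from the livestock N flow, crop residue, mineralization,
#' deposition), indirect volatilization (added to the deposition category)
#' and leaching/runoff, manure management + pasture (combined row), pasture
#' fertilization, residue burning; energy — per-TJ combustion for ten
#' categories plus fugitive; industry — per-tonne production EFs with the
#' two-plant CDM abatement window; waste — protein-based wastewater N load
#' plus solid-waste treatment.
#'
#' @param activity Bundle from [generate_activity()].
#' @param efs Sector EF configuration ([inventory_ef_defaults()]).
#' @param ag_efs Agricultural EF set ([ag_ef_defaults()]).
#' @param registry Region registry.
#' @param abatement Abatement registry ([abatement_registry()]).
#' @return Emission-estimate tibble with `ad_dist`, `ad_cv`, `ef_dist`,
#'   `ef_cv` columns.
#' @export
run_inventory <- function(activity, efs = inventory_ef_defaults(),
                          ag_efs = ag_ef_defaults(), registry = NULL,
                          abatement = abatement_registry()) {
  if (is.null(registry)) registry <- region_registry()

  ## ---- agriculture ----------------------------------------------------
  ef1_tbl <- ag_efs$ef1
  ninp <- dplyr::left_join(activity$n_inputs,
                           registry[c("province", "climate_region")],
                           by = "province") |>
    dplyr::left_join(ef1_tbl, by = c("climate_region", "land_type"))
  ninp$ef1 <- ifelse(is.na(ninp$value),
                     unname(ag_efs$ef1_default[ninp$land_type]), ninp$value)

  # manure N applied to soil, from the livestock flow, split by land type
  lsk <- activity$livestock
  n_ex <- lsk$headcount * (lsk$mass_kg / 1000) * lsk$excretion_rate *
    365 / 1e6
  lsk$n_ex_gg <- n_ex
  applied <- lsk |>
    dplyr::group_by(.data$year, .data$province) |>
    dplyr::summarise(n_applied = sum(.data$n_ex_gg * .data$frac_applied),
                     .groups = "drop")
  upland_share <- ninp$f_sn / stats::ave(ninp$f_sn, ninp$year,
                                         ninp$province, FUN = sum)
  ninp <- dplyr::left_join(ninp, applied, by = c("year", "province"))
  ninp$f_on <- ninp$n_applied * upland_share

  comps <- c(fertilizer_cropland = "f_sn", manure_application = "f_on",
             crop_residue = "f_cr", n_mineralization = "f_som",
             n_deposition = "f_dep")
  direct <- dplyr::bind_rows(lapply(names(comps), function(cat) {
    tibble(year = ninp$year, province = ninp$province, category = cat,
           n2o_n_gg = ninp[[comps[[cat]]]] * ninp$ef1)
  })) |>
    dplyr::group_by(.data$year, .data$province, .data$category) |>
    dplyr::summarise(n2o_n_gg = sum(.data$n2o_n_gg), .groups = "drop")

  # indirect volatilization-redeposition joins the deposition category
  vol <- ninp |>
    dplyr::group_by(.data$year, .data$province) |>
    dplyr::summarise(n2o_n_gg = indirect_deposition(
      sum(.data$f_sn), sum(.data$f_on), ag_efs$frac_gasf, ag_efs$frac_gasm,
      ag_efs$ef4), .groups = "drop") |>
    dplyr::mutate(category = "n_deposition")

  leach <- ninp |>
    dplyr::group_by(.data$year, .data$province) |>
    dplyr::summarise(n2o_n_gg = sum((.data$f_sn + .data$f_on) *
                                      .data$frac_leach * ag_efs$ef5),
                     .groups = "drop") |>
    dplyr::mutate(category = "n_leaching_runoff")

  ef3p <- ag_efs$ef3_pasture
  lsk$ef3_pasture <- unname(ef3p[ifelse(lsk$species %in% names(ef3p),
                                        lsk$species, "other")])
  mms_em <- lsk$n_ex_gg * (lsk$frac_mms_solid * ag_efs$ef3_mms[["solid"]] +
                             lsk$frac_mms_liquid * ag_efs$ef3_mms[["liquid"]])
  past_em <- lsk$n_ex_gg * lsk$frac_pasture * lsk$ef3_pasture
  manure <- lsk |>
    dplyr::mutate(n2o_n_gg = mms_em + past_em) |>
    dplyr::group_by(.data$year, .data$province) |>
    dplyr::summarise(n2o_n_gg = sum(.data$n2o_n_gg), .groups = "drop") |>
    dplyr::mutate(category = "manure_pasture_mgmt")

  pasture_ef1 <- dplyr::left_join(activity$pasture_fert,
                                  registry[c("province", "climate_region")],
                                  by = "province") |>
    dplyr::left_join(ef1_tbl[ef1_tbl$land_type == "upland", ],
                     by = "climate_region")
  pasture_ef1$ef1 <- ifelse(is.na(pasture_ef1$value),
                            ag_efs$ef1_default[["upland"]],
                            pasture_ef1$value)
  pasture <- tibble(year = pasture_ef1$year,
                    province = pasture_ef1$province,
                    n2o_n_gg = pasture_ef1$n_gg * pasture_ef1$ef1,
                    category = "pasture_fertilization")

  burn <- tibble(
    year = activity$residue_burn$year,
    province = activity$residue_burn$province,
    n2o_n_gg = biomass_burning(activity$residue_burn$residue_gg_dm,
                               ag_efs$burning_cf, ag_efs$burning_ef),
    category = "biomass_burning"
  )

  agri <- dplyr::bind_rows(direct, vol, leach, manure, pasture, burn) |>
    dplyr::group_by(.data$year, .data$province, .data$category) |>
    dplyr::summarise(n2o_n_gg = sum(.data$n2o_n_gg), .groups = "drop") |>
    dplyr::mutate(sector = "agriculture")

  ## ---- energy ---------------------------------------------------------
  fu <- activity$fuels
  comb <- fu[fu$category != "fugitive_fuels", ]
  comb$n2o_n_gg <- combustion_emission(comb$value, "TJ",
                                       efs$energy_ef[comb$category])
  fug <- fu[fu$category == "fugitive_fuels", ]
  fug$n2o_n_gg <- fugitive_emission(fug$value, "kt fuel", efs$fugitive_ef,
                                    "kg N2O/kt fuel")
  energy <- dplyr::bind_rows(comb, fug) |>
    dplyr::select("year", "province", "category", "n2o_n_gg") |>
    dplyr::mutate(sector = "energy")

  ## ---- industry -------------------------------------------------------
  pl <- activity$plants
  ab <- abatement[abatement$product == "adipic", ]
  pl$abated <- pl$product == "adipic" & pl$province %in% ab$province &
    pl$year >= min(ab$active_from) & pl$year <= max(ab$active_to)
  j <- match(pl$province, ab$province)
  pl$df <- ifelse(pl$abated, ab$df[j], 0)
  pl$uf <- ifelse(pl$abated, ab$uf[j], 0)
  pl$n2o_n_gg <- production_emission(pl$production_kt,
                                     efs$industry_ef[pl$product],
                                     pl$abated, pl$df, pl$uf)
  industry <- pl |>
    dplyr::mutate(category = ifelse(.data$product == "adipic",
                                    "adipic_acid", "nitric_acid")) |>
    dplyr::select("year", "province", "category", "n2o_n_gg") |>
    dplyr::mutate(sector = "industry")

  ## ---- waste ----------------------------------------------------------
  ww <- activity$waste
  waste <- dplyr::bind_rows(
    tibble(year = ww$year, province = ww$province,
           category = "wastewater",
           n2o_n_gg = wastewater_emission(ww$population, ww$protein_kg,
                                          sludge_n_gg = ww$sludge_n_gg,
                                          ef = efs$wastewater_ef)),
    tibble(year = ww$year, province = ww$province,
           category = "solid_waste_treatment",
           n2o_n_gg = solid_waste_emission(ww$compost_kt, ww$incin_kt,
                                           efs$compost_ef, efs$incin_ef))
  ) |>
    dplyr::mutate(sector = "waste")

  out <- dplyr::bind_rows(agri, energy, industry, waste)
  out <- dplyr::left_join(out, efs$uncertainty, by = "sector")
  out$ad_dist <- "normal"
  out$year <- as.integer(out$year)
  out[, c("year", "province", "sector", "category", "n2o_n_gg",
          "ad_dist", "ad_cv", "ef_dist", "ef_cv")]
}
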