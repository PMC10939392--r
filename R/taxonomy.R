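#' Sector and category taxonomy
#'
#' The inventory uses a closed sector list (natural, energy, industry,
#' agriculture, waste) and a closed category list: 24 anthropogenic
#' categories (11 energy, 2 industry, 9 agriculture, 2 waste) plus the two
#' natural land covers (forest, grassland). Category ids are stable
#' snake_case keys; labels follow the inventory table naming.
#'
#' @return A tibble with columns `sector`, `category`, `label`,
#'   `anthropogenic` (logical).
#' @examples
#' sum(fan_categories()$anthropogenic) # 24
#' @export
fan_categories <- function() {
  tribble_ <- function(sector, ids, labels) {
    tibble(sector = sector, category = ids, label = labels)
  }
  energy <- tribble_("energy",
    c("electricity_generation", "heat_plants", "petroleum_refining",
      "solid_fuel_manufacture", "other_energy_industries",
      "manufacturing_construction", "transport", "residential",
      "agriculture_forestry_fishing", "non_specified", "fugitive_fuels"),
    c("Electricity generation", "Heat plants", "Petroleum refining",
      "Manufacture of solid fuels", "Other energy industries",
      "Manufacturing industries and construction", "Transport", "Residential",
      "Agriculture/forestry/fishing/fish farms", "Non-specified",
      "Fugitive emissions from fuels"))
  industry <- tribble_("industry",
    c("nitric_acid", "adipic_acid"),
    c("Nitric acid production", "Adipic acid production"))
  agriculture <- tribble_("agriculture",
    c("fertilizer_cropland", "n_mineralization", "manure_pasture_mgmt",
      "manure_application", "crop_residue", "n_deposition",
      "pasture_fertilization", "n_leaching_runoff", "biomass_burning"),
    c("Fertilizer application in cropland", "Nitrogen mineralization",
      "Manure left on pasture and manure management",
      "Manure application in cropland", "Crop residue",
      "Nitrogen deposition", "Fertilizer and manure application in pasture",
      "Nitrogen leaching/runoff", "Biomass burning"))
  waste <- tribble_("waste",
    c("solid_waste_treatment", "wastewater"),
    c("Biological treatment of solid waste and waste incineration",
      "Wastewater treatment and discharge"))
  natural <- tribble_("natural",
    c("forest", "grassland"),
    c("Forest", "Grassland"))
  out <- dplyr::bind_rows(energy, industry, agriculture, waste, natural)
  out$anthropogenic <- out$sector != "natural"
  stopifnot(sum(out$anthropogenic) == 24L, !anyDuplicated(out$category))
  out
}

#' Closed sector list
#' @return Character vector of the five sectors.
#' @export
fan_sectors <- function() {
  c("natural", "energy", "industry", "agriculture", "waste")
}

#' Province, region, and climate-region registry
#'
#' Maps each of the 31 mainland provinces to one of the seven reporting
#' regions (Northwest, Southwest, South, East, Central, North, Northeast)
#' and one of six climate regions used to stratify the direct soil emission
#' factor EF1. The climate-region assignment ships as an editable CSV
#' (`inst/extdata/region_map.csv`); the default follows standard
#' administrative groupings, with the South merged into the Central climate
#' zone to form six climate strata.
#'
#' @param path Optional path to an alternative `region_map.csv`
#'   (columns `province`, `region`, `climate_region`).
#' @return A tibble with columns `province`, `region`, `climate_region`.
#' @export
region_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "region_map.csv", package = "n2obudget",
                        mustWork = TRUE)
  }
  map <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  required <- c("province", "region", "climate_region")
  if (!all(required %in% names(map))) {
    abort("region_map.csv must have columns province, region, climate_region.",
          class = "n2o_config_error")
  }
  regions <- c("Northwest", "Southwest", "South", "East", "Central",
               "North", "Northeast")
  bad <- setdiff(unique(map$region), regions)
  if (length(bad) > 0) {
    abort(paste0("Unknown region(s): ", paste(bad, collapse = ", ")),
          class = "n2o_config_error")
  }
  if (anyDuplicated(map$province)) {
    abort("Each province must appear exactly once in the region map.",
          class = "n2o_config_error")
  }
  if (length(unique(map$climate_region)) > 6L) {
    abort("At most six climate regions are supported.",
          class = "n2o_config_error")
  }
  as_tibble(map[required])
}
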