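sector,category,year,n2o_gg,substituted
natural,forest,1980,247.9,FALSE
natural,forest,1990,291.1,FALSE
natural,forest,2000,296.5,FALSE
natural,forest,2010,298.9,FALSE
natural,forest,2020,303.0,FALSE
natural,grassland,1980,69.4,FALSE
natural,grassland,1990,76.2,FALSE
natural,grassland,2000,69.5,FALSE
natural,grassland,2010,68.8,FALSE
natural,grassland,2020,73.3,FALSE
energy,electricity_generation,1980,19.2,TRUE
energy,electricity_generation,1990,52.4,TRUE
energy,electricity_generation,2000,61.8,FALSE
energy,electricity_generation,2010,185.9,FALSE
energy,electricity_generation,2020,241.1,FALSE
energy,heat_plants,1980,0.5,TRUE
energy,heat_plants,1990,2.4,TRUE
energy,heat_plants,2000,3.1,FALSE
energy,heat_plants,2010,10.2,FALSE
energy,heat_plants,2020,19.8,FALSE
energy,petroleum_refining,1980,0.5,TRUE
energy,petroleum_refining,1990,0.1,TRUE
energy,petroleum_refining,2000,0.2,FALSE
energy,petroleum_refining,2010,0.9,FALSE
energy,petroleum_refining,2020,3.4,FALSE
energy,solid_fuel_manufacture,1980,1.0,TRUE
energy,solid_fuel_manufacture,1990,2.2,TRUE
energy,solid_fuel_manufacture,2000,1.8,FALSE
energy,solid_fuel_manufacture,2010,5.9,FALSE
energy,solid_fuel_manufacture,2020,7.2,FALSE
energy,other_energy_industries,1980,0.1,TRUE
energy,other_energy_industries,1990,0.4,TRUE
energy,other_energy_industries,2000,0.6,FALSE
energy,other_energy_industries,2010,0.3,FALSE
energy,other_energy_industries,2020,1.3,FALSE
energy,manufacturing_construction,1980,15.1,TRUE
energy,manufacturing_construction,1990,24.7,TRUE
energy,manufacturing_construction,2000,23.9,FALSE
energy,manufacturing_construction,2010,45.5,FALSE
energy,manufacturing_construction,2020,36.6,FALSE
energy,transport,1980,4.1,TRUE
energy,transport,1990,4.2,TRUE
energy,transport,2000,5.3,FALSE
energy,transport,2010,17.1,FALSE
energy,transport,2020,20.0,FALSE
energy,residential,1980,4.3,TRUE
energy,residential,1990,5.7,TRUE
energy,residential,2000,4.3,FALSE
energy,residential,2010,5.6,FALSE
energy,residential,2020,4.5,FALSE
energy,agriculture_forestry_fishing,1980,0.9,TRUE
energy,agriculture_forestry_fishing,1990,1.1,TRUE
energy,agriculture_forestry_fishing,2000,1.2,FALSE
energy,agriculture_forestry_fishing,2010,1.4,FALSE
energy,agriculture_forestry_fishing,2020,1.7,FALSE
energy,non_specified,1980,0.2,TRUE
energy,non_specified,1990,1.0,TRUE
energy,non_specified,2000,0.9,FALSE
energy,non_specified,2010,2.0,FALSE
energy,non_specified,2020,0.8,FALSE
energy,fugitive_fuels,1980,0.6,TRUE
energy,fugitive_fuels,1990,0.3,TRUE
energy,fugitive_fuels,2000,0.3,FALSE
energy,fugitive_fuels,2010,0.1,FALSE
energy,fugitive_fuels,2020,0.0,FALSE
industry,nitric_acid,2000,10.6,TRUE
industry,nitric_acid,2010,38.3,FALSE
industry,nitric_acid,2020,38.7,FALSE
industry,adipic_acid,2000,34.5,TRUE
industry,adipic_acid,2010,129.8,FALSE
industry,adipic_acid,2020,468.0,FALSE
agriculture,fertilizer_cropland,1980,197.7,FALSE
agriculture,fertilizer_cropland,1990,305.4,FALSE
agriculture,fertilizer_cropland,2000,356.8,FALSE
agriculture,fertilizer_cropland,2010,479.5,FALSE
agriculture,fertilizer_cropland,2020,413.1,FALSE
agriculture,n_mineralization,1980,82.1,FALSE
agriculture,n_mineralization,1990,122.6,FALSE
agriculture,n_mineralization,2000,124.7,FALSE
agriculture,n_mineralization,2010,124.3,FALSE
agriculture,n_mineralization,2020,170.0,FALSE
agriculture,manure_pasture_mgmt,1980,79.7,FALSE
agriculture,manure_pasture_mgmt,1990,99.7,FALSE
agriculture,manure_pasture_mgmt,2000,119.3,FALSE
agriculture,manure_pasture_mgmt,2010,91.4,FALSE
agriculture,manure_pasture_mgmt,2020,91.7,FALSE
agriculture,manure_application,1980,39.0,FALSE
agriculture,manure_application,1990,49.7,FALSE
agriculture,manure_application,2000,71.7,FALSE
agriculture,manure_application,2010,78.5,FALSE
agriculture,manure_application,2020,64.9,FALSE
agriculture,crop_residue,1980,30.8,FALSE
agriculture,crop_residue,1990,49.1,FALSE
agriculture,crop_residue,2000,49.6,FALSE
agriculture,crop_residue,2010,59.5,FALSE
agriculture,crop_residue,2020,70.6,FALSE
agriculture,n_deposition,1980,31.7,FALSE
agriculture,n_deposition,1990,46.1,FALSE
agriculture,n_deposition,2000,49.8,FALSE
agriculture,n_deposition,2010,56.8,FALSE
agriculture,n_deposition,2020,81.5,FALSE
agriculture,pasture_fertilization,1980,7.7,FALSE
agriculture,pasture_fertilization,1990,14.3,FALSE
agriculture,pasture_fertilization,2000,20.8,FALSE
agriculture,pasture_fertilization,2010,30.4,FALSE
agriculture,pasture_fertilization,2020,25.9,FALSE
agriculture,n_leaching_runoff,1980,10.7,FALSE
agriculture,n_leaching_runoff,1990,17.9,FALSE
agriculture,n_leaching_runoff,2000,21.6,FALSE
agriculture,n_leaching_runoff,2010,25.1,FALSE
agriculture,n_leaching_runoff,2020,23.5,FALSE
agriculture,biomass_burning,1980,2.3,FALSE
agriculture,biomass_burning,1990,3.6,FALSE
agriculture,biomass_burning,2000,3.8,FALSE
agriculture,biomass_burning,2010,4.5,FALSE
agriculture,biomass_burning,2020,5.3,FALSE
waste,solid_waste_treatment,2000,0.1,FALSE
waste,solid_waste_treatment,2010,2.0,FALSE
waste,solid_waste_treatment,2020,10.1,TRUE
waste,wastewater,1980,44.2,TRUE
waste,wastewater,1990,59.5,FALSE
waste,wastewater,2000,85.3,FALSE
waste,wastewater,2010,102.1,FALSE
waste,wastewater,2020,118.8,TRUE
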