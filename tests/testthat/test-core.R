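test_that("emission composes activity and EF units onto the N2O-N basis", {
  # zero activity
  expect_equal(emission(0, "Gg N", 0.01, "kg N2O-N/kg N"), 0)
  # hand arithmetic: 100 Gg N * 0.01 kg N2O-N/kg N
  expect_equal(emission(100, "Gg N", 0.01, "kg N2O-N/kg N"), 1.0)
  # product-basis EF on the N2O basis: 500 kt * 0.3 t N2O/t = 150 kt N2O
  expect_equal(emission(500, "kt product", 0.3, "t N2O/t product"),
               150 * 28 / 44, tolerance = 1e-12)
  # linearity in AD
  for (k in c(0, 0.5, 2, 17)) {
    expect_equal(emission(k * 123.4, "Gg N", 0.011, "kg N2O-N/kg N"),
                 k * emission(123.4, "Gg N", 0.011, "kg N2O-N/kg N"))
  }
})

test_that("emission rejects incompatible or unknown units and negative inputs", {
  expect_error(emission(1, "Gg N", 1, "kg N2O/TJ"), class = "n2o_unit_error")
  err <- tryCatch(emission(1, "Gg N", 1, "kg N2O/t product"),
                  error = function(e) conditionMessage(e))
  expect_match(err, "Gg N")
  expect_match(err, "t product")
  expect_error(emission(1, "furlong N", 1, "kg N2O-N/kg N"),
               class = "n2o_unit_error")
  expect_error(emission(-1, "Gg N", 1, "kg N2O-N/kg N"),
               class = "n2o_domain_error")
  expect_error(emission(1, "Gg N", 1, "kg N/kg N"), class = "n2o_unit_error")
})

test_that("emission matches an independent spreadsheet-style oracle", {
  set.seed(42)
  ad_units <- c("Gg N", "kt product", "t dm", "TJ", "kg N")
  ef_units <- c("kg N2O-N/kg N", "t N2O/t product", "kg N2O/t dm",
                "kg N2O/TJ", "g N2O-N/kg N")
  for (i in 1:100) {
    j <- sample(5, 1)
    ad <- stats::runif(1, 0, 1e4)
    ef <- stats::runif(1, 0, 2)
    expect_equal(emission(ad, ad_units[j], ef, ef_units[j]),
                 oracle_emission(ad, ad_units[j], ef, ef_units[j]),
                 tolerance = 1e-9)
  }
})

test_that("N2O-N / N2O conversion uses 44/28 and round-trips", {
  expect_equal(n2o_n_to_n2o(28), 44)
  expect_equal(n2o_n_to_n2o(0), 0)
  expect_equal(n2o_n_to_n2o(1), 44 / 28)
  x <- stats::runif(50, 0, 1e4)
  expect_equal(n2o_to_n2o_n(n2o_n_to_n2o(x)), x, tolerance = 1e-12)
  expect_error(n2o_n_to_n2o(-1), class = "n2o_domain_error")
  expect_error(n2o_to_n2o_n(-1), class = "n2o_domain_error")
})

test_that("EF lookup matches stratum keys exactly and reports misses", {
  efs <- tibble::tibble(
    category = c("fertilizer_cropland", "fertilizer_cropland", "wastewater"),
    stratum = c("climate_region=East;land_type=upland",
                "land_type=paddy;climate_region=East", ""),
    value = c(0.0157, 0.0161, 0.005), unit = "kg N2O-N/kg N"
  )
  hit <- ef_lookup(efs, "fertilizer_cropland",
                   c(land_type = "upland", climate_region = "East"))
  expect_equal(hit$value, 0.0157)
  # key order in the table must not matter
  hit2 <- ef_lookup(efs, "fertilizer_cropland",
                    c(climate_region = "East", land_type = "paddy"))
  expect_equal(hit2$value, 0.0161)
  expect_equal(ef_lookup(efs, "wastewater")$value, 0.005)
  expect_error(ef_lookup(efs, "fertilizer_cropland",
                         c(climate_region = "Mars", land_type = "upland")),
               class = "n2o_lookup_error")
})

test_that("gap filling substitutes the nearest year and flags it", {
  # a sector whose statistics begin in 1985
  filled <- gap_fill(c(`1985` = 46.5, `1995` = 94.6), years = 1980:1995)
  expect_equal(filled$value[filled$year == 1980], 46.5)
  expect_true(filled$substituted[filled$year == 1980])
  expect_false(filled$substituted[filled$year == 1985])
  # a single 1981 observation serves 1980
  one <- gap_fill(c(`1981` = 44.2), years = 1980:1981)
  expect_equal(one$value[one$year == 1980], 44.2)
  # ties break toward the later year
  tie <- gap_fill(c(`1990` = 1, `1992` = 2), years = 1990:1992)
  expect_equal(tie$value[tie$year == 1991], 2)
  # fully populated series is the identity
  full <- gap_fill(c(`2000` = 1, `2001` = 2, `2002` = 3))
  expect_equal(full$value, c(1, 2, 3))
  expect_false(any(full$substituted))
  expect_error(gap_fill(numeric(0)), class = "n2o_domain_error")
})

test_that("aggregation sums exactly, reports Gg N2O, and validates keys", {
  # printed sector subtotals as inputs reproduce the national totals
  agg <- aggregate_emissions(subtotal_estimates(), by = "year")
  expect_equal(agg$n2o_gg[agg$year == 2020], 2295.0, tolerance = 1e-9)
  anthro <- aggregate_emissions(
    subtotal_estimates()[subtotal_estimates()$sector != "natural", ],
    by = "year")
  expect_equal(anthro$n2o_gg[anthro$year == 2020], 1918.8, tolerance = 1e-9)
  # empty collection
  expect_equal(aggregate_emissions(subtotal_estimates()[0, ], by = character()
                                   )$n2o_gg, 0)
  expect_error(aggregate_emissions(subtotal_estimates(), by = "color"),
               class = "n2o_lookup_error")
})

test_that("aggregation is additive over any partition of categories", {
  set.seed(7)
  est <- emission_estimate(
    year = sample(1980:2020, 200, TRUE),
    province = sample(c("Henan", "Hebei", "Anhui"), 200, TRUE),
    sector = "agriculture",
    category = sample(letters[1:6], 200, TRUE),
    n2o_n_gg = stats::runif(200, 0, 10)
  )
  whole <- aggregate_emissions(est, by = character())$n2o_n_gg
  parts <- split(seq_len(200), sample(3, 200, TRUE))
  part_sum <- sum(vapply(parts, function(i) {
    aggregate_emissions(est[i, ], by = character())$n2o_n_gg
  }, numeric(1)))
  expect_equal(part_sum, whole, tolerance = 1e-9)
  # grouping by region joins the registry
  reg <- aggregate_emissions(est, by = c("region"))
  expect_true(all(reg$region %in% c("Central", "North", "East")))
})

test_that("activity and EF CSV readers validate their schemas", {
  tmp <- withr::local_tempdir()
  act <- tibble::tibble(year = 2000L, province = "Henan",
                        sector = "agriculture",
                        category = "fertilizer_cropland",
                        variable = "fertilizer_n", value = 10, unit = "Gg N")
  readr::write_csv(act, file.path(tmp, "activity.csv"))
  expect_equal(read_activity_csv(file.path(tmp, "activity.csv"))$value, 10)
  readr::write_csv(act[, -6], file.path(tmp, "bad.csv"))
  expect_error(read_activity_csv(file.path(tmp, "bad.csv")),
               class = "n2o_config_error")
  ef <- tibble::tibble(category = "wastewater", stratum = NA, value = 0.005,
                       unit = "kg N2O-N/kg N", low = 0.001, high = 0.02,
                       distribution = "lognormal")
  readr::write_csv(ef, file.path(tmp, "ef.csv"))
  got <- read_ef_csv(file.path(tmp, "ef.csv"))
  expect_equal(got$stratum, "")
  ef_bad <- dplyr::mutate(ef, low = 0.01)
  readr::write_csv(ef_bad, file.path(tmp, "ef_bad.csv"))
  expect_error(read_ef_csv(file.path(tmp, "ef_bad.csv")),
               class = "n2o_domain_error")
})
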