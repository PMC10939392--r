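#' Load the printed five-snapshot inventory fixture
#'
#' Returns the published sub-source emissions for 1980, 1990, 2000, 2010
#' and 2020 (Gg N2O, national level) as an emission-estimate table.
#' Only sub-source rows are stored; subtotal and total rows are recomputed
#' with [aggregate_emissions()] and land within +/- 0.2 Gg of the printed
#' values (line-item rounding). Cells borrowed from neighbouring years in
#' the source (energy 1980/1990 from 1985/1995, industry 2000 from 2002,
#' wastewater 1980/2020 from 1981/2019) carry `substituted = TRUE`; years
#' in which a category did not yet report are absent, not zero.
#'
#' @return Emission-estimate tibble (province `"national"`), with both
#'   `n2o_gg` and the internal `n2o_n_gg`.
#' @examples
#' t1 <- load_table1_fixture()
#' aggregate_emissions(t1, by = c("year", "sector"))
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_emissions.csv",
                      package = "n2obudget", mustWork = TRUE)
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         sector = "c", category = "c", year = "i",
                         n2o_gg = "d", substituted = "l"))
  est <- emission_estimate(
    year = x$year, province = "national", sector = x$sector,
    category = x$category, n2o_n_gg = n2o_to_n2o_n(x$n2o_gg),
    substituted = x$substituted
  )
  est$n2o_gg <- x$n2o_gg
  est
}
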