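#' Industrial N2O from adipic and nitric acid production
#'
#' Production emissions with plant-level abatement:
#' `P * EF * (1 - DF * UF)` when abatement equipment is installed, where DF
#' is the destruction factor of the device and UF its utilization, else
#' `P * EF`. Thermal/catalytic devices destroy 80-98% of process N2O, so an
#' installed, fully used device reduces the plant's emission by DF.
#'
#' @param production_kt Production (kt of product), non-negative.
#' @param ef EF in kg N2O per t product (typical defaults: 300 for adipic
#'   acid, 9 for nitric acid).
#' @param abated Logical, abatement installed and active this year.
#' @param df Destruction factor in `[0, 1]`.
#' @param uf Utilization factor in `[0, 1]`.
#' @return Emission in Gg N2O-N.
#' @examples
#' production_emission(500, 300)                      # unabated
#' production_emission(500, 300, TRUE, 0.9, 0.95)     # two-plant CDM case
#' @export
production_emission <- function(production_kt, ef, abated = FALSE,
                                df = 0, uf = 0) {
  if (any(df < 0 | df > 1 | uf < 0 | uf > 1)) {
    abort("Destruction and utilization factors must lie in [0, 1].",
          class = "n2o_domain_error")
  }
  base <- emission(production_kt, "kt product", ef, "kg N2O/t product")
  scale <- ifelse(abated, 1 - df * uf, 1)
  base * scale
}

#' Registry of abated plants
#'
#' Two adipic-acid plants installed N2O abatement under the Clean
#' Development Mechanism, whose first commitment period covered 2008-2012.
#' Whether abatement continued after 2012 is unknown (high cost); the
#' default assumption is that it did not, controlled by
#' `continue_after_2012`.
#'
#' @param continue_after_2012 Logical scenario switch (default `FALSE`).
#' @return Tibble with `plant`, `province`, `product`, `df`, `uf`,
#'   `active_from`, `active_to`.
#' @export
abatement_registry <- function(continue_after_2012 = FALSE) {
  tibble(
    plant = c("Henan Shenma Nylon Chemical", "Liaoyang Petrochemical"),
    province = c("Henan", "Liaoning"),
    product = "adipic",
    df = 0.9,
    uf = 0.9,
    active_from = 2008L,
    active_to = if (continue_after_2012) 2020L else 2012L
  )
}
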