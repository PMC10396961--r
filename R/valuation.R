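#' Discounting specification for harvest-year-equivalent emissions
#'
#' Annual changes in atmospheric carbon caused by a harvest are valued
#' back to the year of harvest with discount rate `d` over `N` years:
#' `PDV = sum_{t=0}^{N} delta[t] / (1 + d)^t`. With `d = 0` the PDV is the
#' physical change in atmospheric carbon at the end of the period.
#'
#' @param d Discount rate per year, in \[0, 0.10\] (default 0.04).
#' @param N Valuation horizon in years after harvest (default 40;
#'   100 also commonly used). Must be in 1..200.
#' @return An object of class `discount_spec`.
#' @export
discount_spec <- function(d = 0.04, N = 40) {
  if (!is.numeric(d) || d < 0 || d > 0.10) {
    abort("`d` must be in [0, 0.10].", class = "woodcarbon_error")
  }
  if (!is.numeric(N) || N < 1 || N > 200 || N != round(N)) {
    abort("`N` must be an integer in 1..200.", class = "woodcarbon_error")
  }
  structure(list(d = d, N = as.integer(N)), class = "discount_spec")
}

#' Present discounted value of an annual carbon-change series
#'
#' Values a series of annual atmospheric changes (t = 0 is the harvest
#' year, positive = emission) as a single harvest-year-equivalent
#' quantity. The series is truncated or zero-padded to `N + 1` terms; no
#' regrowth is extrapolated beyond what was simulated.
#'
#' @param deltas Numeric series of annual changes (tC/ha/yr), `deltas[1]`
#'   being the harvest year.
#' @param spec A [discount_spec()].
#' @return Harvest-year-equivalent cost (same unit as `deltas`, per ha).
#' @examples
#' pdv(c(10, -5), discount_spec(d = 0.04, N = 40))
#' @export
pdv <- function(deltas, spec = discount_spec()) {
  stopifnot(is.numeric(deltas), length(deltas) >= 1,
            inherits(spec, "discount_spec"))
  n <- spec$N + 1L
  x <- rep(0, n)
  k <- min(n, length(deltas))
  x[seq_len(k)] <- deltas[seq_len(k)]
  sum(x / (1 + spec$d)^(0:spec$N))
}

#' Harvest ledger: per-year, per-forest-type PDVs and areas
#'
#' @param pdv_by_year A data frame with columns `year` (harvest calendar
#'   year), `forest_type` (`"secondary"` or `"plantation"`), `pdv_per_ha`
#'   (tC/ha or t CO2e/ha) and `area_ha` (hectares harvested that year).
#' @return The validated tibble with class `harvest_ledger`.
#' @export
harvest_ledger <- function(pdv_by_year) {
  need <- c("year", "forest_type", "pdv_per_ha", "area_ha")
  stopifnot(is.data.frame(pdv_by_year))
  if (!all(need %in% names(pdv_by_year))) {
    abort(paste0("Ledger needs columns: ", paste(need, collapse = ", ")),
          class = "woodcarbon_error")
  }
  if (any(pdv_by_year$area_ha < 0)) {
    abort("Ledger areas must be >= 0.", class = "woodcarbon_error")
  }
  out <- tibble::as_tibble(pdv_by_year)
  class(out) <- c("harvest_ledger", class(out))
  out
}

#' Total discounted carbon cost across harvest years and forest types
#'
#' Multiplies the per-hectare harvest-year-equivalent cost of each forest
#' type in each harvest year by the new area of that type harvested that
#' year, and sums over both.
#'
#' @param ledger A [harvest_ledger()] (or a data frame with the same
#'   columns).
#' @return Total PDV (unit of `pdv_per_ha` times hectares).
#' @export
aggregate_pdv <- function(ledger) {
  ledger <- harvest_ledger(ledger)
  sum(ledger$pdv_per_ha * ledger$area_ha)
}

#' Annualized carbon cost in Gt CO2e per year
#'
#' Converts a total discounted carbon cost in tC to an average annual
#' flux in Gt CO2e/yr over a study period: `pdv_total * 44/12 / years`,
#' scaled to gigatonnes.
#'
#' @param pdv_total Total cost in tC (already CO2e-weighted series should
#'   use [annualize_co2e()] instead).
#' @param years Length of the study period (default 40 for 2010-2050).
#' @return Gt CO2e per year.
#' @export
annualize <- function(pdv_total, years = 40) {
  if (years <= 0) abort("`years` must be > 0.", class = "woodcarbon_error")
  pdv_total * CO2_PER_C / years / 1e9
}

#' @rdname annualize
#' @param pdv_total_co2e Total cost already in t CO2e.
#' @export
annualize_co2e <- function(pdv_total_co2e, years = 40) {
  if (years <= 0) abort("`years` must be > 0.", class = "woodcarbon_error")
  pdv_total_co2e / years / 1e9
}

#' Substitution factors for avoided production emissions
#'
#' Wood used in construction displaces concrete and steel, saving an
#' estimated 1.2 tC of production (fossil/process) emissions per tC of
#' wood; wood fuel displacing propane saves an estimated 0.175 tC per tC
#' of wood carbon. These savings are reported separately from biogenic
#' carbon costs and are never netted against them: substitution does not
#' alter the absolute emissions of wood harvest.
#'
#' @param construction tC saved per tC of wood used in construction
#'   (default 1.2).
#' @param wood_fuel tC saved per tC of wood fuel (default 0.175).
#' @param construction_share Share of long-lived-product carbon used in
#'   construction (default 1).
#' @return An object of class `substitution_factors`.
#' @export
substitution_factors <- function(construction = 1.2, wood_fuel = 0.175,
                                 construction_share = 1) {
  if (construction < 0 || wood_fuel < 0) {
    abort("Substitution factors must be >= 0.", class = "woodcarbon_error")
  }
  if (construction_share < 0 || construction_share > 1) {
    abort("`construction_share` must be in [0, 1].",
          class = "woodcarbon_error")
  }
  structure(list(construction = construction, wood_fuel = wood_fuel,
                 construction_share = construction_share),
            class = "substitution_factors")
}

#' Substitution benefit of wood use
#'
#' @param llp_carbon Carbon in long-lived products (tC); the
#'   `construction_share` of it earns the construction factor.
#' @param wood_fuel_carbon Carbon in wood fuel (tC).
#' @param factors A [substitution_factors()].
#' @return tC of avoided production emissions.
#' @export
substitution_benefit <- function(llp_carbon, wood_fuel_carbon,
                                 factors = substitution_factors()) {
  stopifnot(inherits(factors, "substitution_factors"))
  if (any(llp_carbon < 0) || any(wood_fuel_carbon < 0)) {
    abort("Wood carbon must be >= 0.", class = "woodcarbon_error")
  }
  llp_carbon * factors$construction_share * factors$construction +
    wood_fuel_carbon * factors$wood_fuel
}
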