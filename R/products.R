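#' Product allocation shares for harvested carbon
#'
#' Harvested wood carbon is allocated to four consumption categories:
#' long-lived products (`llp`: construction wood, panels and other
#' industrial roundwood), short-lived products (`slp`: paper and
#' paperboard), wood fuel (`vslp_wfl`: wood harvested deliberately for
#' energy) and industrial fuel (`vslp_ind`: manufacturing waste burned for
#' energy). Shares must sum to one.
#'
#' @param llp,slp,vslp_wfl,vslp_ind Fractions in \[0, 1\] summing to 1.
#' @return An object of class `product_shares`.
#' @export
product_shares <- function(llp, slp, vslp_wfl, vslp_ind) {
  x <- c(llp = llp, slp = slp, vslp_wfl = vslp_wfl, vslp_ind = vslp_ind)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort("Product shares must be fractions in [0, 1].",
          class = "woodcarbon_error")
  }
  if (abs(sum(x) - 1) > 1e-9) {
    abort(sprintf("Product shares must sum to 1 (got %.12f).", sum(x)),
          class = "woodcarbon_error")
  }
  structure(as.list(x), class = "product_shares")
}

#' Volume/carbon conversion and roundwood-requirement table
#'
#' Holds the constants mapping consumed wood-product volumes (expressed in
#' roundwood equivalents, RWE) back to the roundwood harvest needed to
#' supply them, and mapping volumes to carbon.
#'
#' `ratio_llp` and `ratio_slp` are m3 of roundwood harvested per m3 of
#' product consumed (>= 1 where processing loses wood); the pulp ratio
#' applies only to the virgin-pulp share of paper. `pulp_share_virgin` is
#' the share of paper produced from wood pulp (default 0.40; the remainder
#' comes from recovered paper and other pulp and requires no harvest).
#' Processing losses implied by the ratios become burnable co-product
#' waste that satisfies industrial-fuel demand before any extra harvest.
#'
#' @param wood_density Dry matter per green volume (t DM/m3, default 0.48).
#' @param carbon_fraction Carbon per unit dry matter (default 0.5).
#' @param pulp_share_virgin Share of paper from virgin wood pulp
#'   (default 0.40).
#' @param ratio_llp,ratio_slp,ratio_vslp_wfl,ratio_vslp_ind Roundwood
#'   required per unit consumption, by product (m3/m3).
#' @return An object of class `conversion_table`.
#' @export
conversion_table <- function(wood_density = 0.48,
                             carbon_fraction = 0.5,
                             pulp_share_virgin = 0.40,
                             ratio_llp = 1.3,
                             ratio_slp = 1.2,
                             ratio_vslp_wfl = 1,
                             ratio_vslp_ind = 1) {
  if (wood_density <= 0) abort("`wood_density` must be > 0.",
                               class = "woodcarbon_error")
  if (carbon_fraction <= 0 || carbon_fraction >= 1) {
    abort("`carbon_fraction` must be in (0, 1).", class = "woodcarbon_error")
  }
  if (pulp_share_virgin < 0 || pulp_share_virgin > 1) {
    abort("`pulp_share_virgin` must be in [0, 1].", class = "woodcarbon_error")
  }
  ratios <- c(llp = ratio_llp, slp = ratio_slp,
              vslp_wfl = ratio_vslp_wfl, vslp_ind = ratio_vslp_ind)
  if (any(ratios < 1)) {
    abort("Roundwood-per-consumption ratios must be >= 1.",
          class = "woodcarbon_error")
  }
  structure(list(wood_density = wood_density,
                 carbon_fraction = carbon_fraction,
                 pulp_share_virgin = pulp_share_virgin,
                 ratios = ratios),
            class = "conversion_table")
}

#' Convert roundwood-equivalent volume to carbon (and back)
#'
#' Carbon = volume x wood density x carbon fraction.
#'
#' @param volume Volume in m3 RWE (vectorised, >= 0).
#' @param table A [conversion_table()].
#' @return Carbon in tonnes.
#' @export
volume_to_carbon <- function(volume, table = conversion_table()) {
  stopifnot(is.numeric(volume), inherits(table, "conversion_table"))
  if (any(volume < 0)) abort("`volume` must be >= 0.",
                             class = "woodcarbon_error")
  volume * table$wood_density * table$carbon_fraction
}

#' @rdname volume_to_carbon
#' @param carbon Carbon in tonnes (vectorised, >= 0).
#' @export
carbon_to_volume <- function(carbon, table = conversion_table()) {
  stopifnot(is.numeric(carbon), inherits(table, "conversion_table"))
  if (any(carbon < 0)) abort("`carbon` must be >= 0.",
                             class = "woodcarbon_error")
  carbon / (table$wood_density * table$carbon_fraction)
}

#' Roundwood harvest required to meet product consumption
#'
#' Maps consumption of the four product categories (m3 RWE) to the
#' roundwood harvest required to supply it. Paper demand is first reduced
#' to its virgin-pulp share; per-product ratios add processing losses; and
#' industrial-fuel demand is met from the co-product waste those losses
#' generate before any additional harvest is required.
#'
#' @param consumption A data frame with columns `product`
#'   (`llp`, `slp`, `vslp_wfl`, `vslp_ind`) and `consumption` (m3 RWE).
#'   Extra grouping columns (e.g. `country`, `year`) are preserved and the
#'   computation is done per group.
#' @param table A [conversion_table()].
#' @return A tibble, one row per group, with columns `harvest_llp`,
#'   `harvest_slp`, `harvest_vslp_wfl`, `harvest_vslp_ind` (additional
#'   harvest for industrial fuel beyond waste), `coproduct_waste` and
#'   `harvest_total` (m3 roundwood).
#' @export
roundwood_from_consumption <- function(consumption,
                                       table = conversion_table()) {
  stopifnot(is.data.frame(consumption),
            all(c("product", "consumption") %in% names(consumption)),
            inherits(table, "conversion_table"))
  bad <- setdiff(unique(consumption$product), names(table$ratios))
  if (length(bad) > 0) {
    abort(paste0("No roundwood ratio for product(s): ",
                 paste(bad, collapse = ", ")),
          class = "woodcarbon_error")
  }
  if (any(consumption$consumption < 0)) {
    abort("`consumption` must be >= 0.", class = "woodcarbon_error")
  }
  keys <- setdiff(names(consumption), c("product", "consumption"))
  wide <- consumption |>
    tidyr::pivot_wider(names_from = "product",
                       values_from = "consumption",
                       values_fill = 0)
  for (p in names(table$ratios)) {
    if (!p %in% names(wide)) wide[[p]] <- 0
  }
  r <- table$ratios
  wide |>
    dplyr::mutate(
      harvest_llp = .data$llp * r[["llp"]],
      virgin_paper = .data$slp * table$pulp_share_virgin,
      harvest_slp = .data$virgin_paper * r[["slp"]],
      harvest_vslp_wfl = .data$vslp_wfl * r[["vslp_wfl"]],
      coproduct_waste = (.data$harvest_llp - .data$llp) +
        (.data$harvest_slp - .data$virgin_paper),
      harvest_vslp_ind = pmax(0, .data$vslp_ind * r[["vslp_ind"]] -
                                   .data$coproduct_waste),
      harvest_total = .data$harvest_llp + .data$harvest_slp +
        .data$harvest_vslp_wfl + .data$harvest_vslp_ind
    ) |>
    dplyr::select(dplyr::all_of(keys), "harvest_llp", "harvest_slp",
                  "harvest_vslp_wfl", "harvest_vslp_ind",
                  "coproduct_waste", "harvest_total") |>
    tibble::as_tibble()
}

#' Landfill decay parameters
#'
#' Long-lived products route to landfills as they decay; landfills release
#' carbon slowly, and a fraction of that release is methane, weighted by
#' its 100-year global warming potential when reporting CO2 equivalents.
#'
#' @param landfill_fraction_of_llp_decay Share of decayed LLP carbon that
#'   enters the landfill pool (the rest is released as CO2 directly).
#' @param methane_fraction Share of landfill carbon release emitted as CH4.
#' @param gwp100_ch4 CO2e per tonne CH4 over 100 years (default 28).
#' @return An object of class `landfill_params`.
#' @export
landfill_params <- function(landfill_fraction_of_llp_decay = 0.5,
                            methane_fraction = 0.5,
                            gwp100_ch4 = 28) {
  f <- c(landfill_fraction_of_llp_decay, methane_fraction)
  if (any(f < 0 | f > 1)) {
    abort("Landfill fractions must be in [0, 1].", class = "woodcarbon_error")
  }
  if (gwp100_ch4 <= 1) abort("`gwp100_ch4` must be > 1.",
                             class = "woodcarbon_error")
  structure(list(landfill_fraction_of_llp_decay = landfill_fraction_of_llp_decay,
                 methane_fraction = methane_fraction,
                 gwp100_ch4 = gwp100_ch4),
            class = "landfill_params")
}

#' One annual step of the landfill pool
#'
#' Applies first-order decay to the landfill stock and splits the released
#' carbon into CO2-C and CH4-C. CO2 equivalents weight the methane part by
#' its GWP100: `co2e = co2_c * 44/12 + ch4_c * 16/12 * gwp100_ch4`.
#'
#' @param stock Landfill carbon stock (tC, vectorised, >= 0).
#' @param params A [landfill_params()].
#' @param half_life Landfill half-life (years, > 0).
#' @return A tibble with columns `remaining`, `co2_c`, `ch4_c` (tC) and
#'   `co2e` (t CO2e).
#' @export
landfill_step <- function(stock, params = landfill_params(), half_life) {
  stopifnot(inherits(params, "landfill_params"))
  d <- decay_step(stock, half_life)
  ch4_c <- d$released * params$methane_fraction
  co2_c <- d$released - ch4_c
  tibble::tibble(
    remaining = d$remaining,
    co2_c = co2_c,
    ch4_c = ch4_c,
    co2e = co2_c * CO2_PER_C + ch4_c * CH4_PER_C * params$gwp100_ch4
  )
}
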