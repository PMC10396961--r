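#' Future wood-supply scenario configurations
#'
#' Seven stylised supply scenarios. All share the same demand projection
#' except scenario 7:
#' 1. baseline — plantations first, remainder from middle-aged secondary
#'    forests that regrow as secondary forest;
#' 2. conversion — harvested secondary forests are converted to
#'    productive plantations that also supply wood in later years;
#' 3. mixed harvest — half of secondary harvest area comes from mature
#'    stands (40 years older than middle-aged);
#' 4. new tropical plantations — 2 Mha/yr of tropical agricultural land
#'    is converted to plantations (their no-harvest counterfactual is
#'    secondary regrowth from bare land);
#' 5. high plantation productivity — existing plantation growth +25%;
#' 6. higher harvest efficiency — tropical secondary harvests use a
#'    high-efficiency recovery rate;
#' 7. reduced wood fuel — wood-fuel consumption declines linearly to 50%
#'    of its 2050 baseline projection.
#'
#' @param id Scenario id, 1-7.
#' @param high_efficiency Recovery rate used for tropical secondary
#'   harvests in scenario 6 (default 0.8).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(id, high_efficiency = 0.8) {
  if (!id %in% 1:7) abort("`id` must be 1..7.", class = "woodcarbon_error")
  names <- c("secondary harvest and regrowth",
             "secondary harvest and conversion",
             "secondary mixed harvest",
             "new tropical plantations",
             "high plantation productivity",
             "higher harvest efficiency",
             "reduced wood fuel demand")
  structure(list(
    id = as.integer(id),
    name = names[id],
    regrow_secondary_as = if (id == 2) "plantation" else "secondary",
    mature_fraction = if (id == 3) 0.5 else 0,
    new_tropical_plantations_ha_yr = if (id == 4) 2e6 else 0,
    plantation_productivity_multiplier = if (id == 5) 1.25 else 1,
    tropical_efficiency = if (id == 6) high_efficiency else NA_real_,
    wood_fuel_multiplier_2050 = if (id == 7) 0.5 else 1
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %d: %s\n", x$id, x$name))
  invisible(x)
}

#' Clear-cut-equivalent area for a harvested volume
#'
#' Hectares that must be clear-cut, at a stated per-hectare yield, to
#' supply a volume; a normalisation that sidesteps the unknown footprint
#' of selective harvest.
#'
#' @param volume Harvested volume (m3, >= 0, vectorised).
#' @param yield_per_ha Recoverable yield (m3/ha, > 0).
#' @return Hectares.
#' @export
clearcut_equivalent_area <- function(volume, yield_per_ha) {
  if (any(yield_per_ha <= 0)) abort("`yield_per_ha` must be > 0.",
                                    class = "woodcarbon_error")
  if (any(volume < 0)) abort("`volume` must be >= 0.",
                             class = "woodcarbon_error")
  volume / yield_per_ha
}

#' Scale a 30-country total to a global estimate
#'
#' National analyses cover the 30 countries producing 80% of the world's
#' wood; additive totals are divided by 0.8 for a global figure.
#'
#' @param total_30 Any additive quantity (vectorised, >= 0).
#' @param coverage Share of the global total covered (default 0.8).
#' @return Global estimate.
#' @export
scale_global <- function(total_30, coverage = 0.8) {
  if (coverage <= 0 || coverage > 1) {
    abort("`coverage` must be in (0, 1].", class = "woodcarbon_error")
  }
  total_30 / coverage
}

#' Bundle of inputs for a scenario run
#'
#' @param profiles Country profile tibble; required columns: `country`,
#'   `tropical`, `plantation_area_2010`, `plant_young`, `plant_old`,
#'   `sec_young`, `sec_old`, `root_shoot_coef`, `root_shoot_exp`,
#'   `slash_plantation`, `slash_secondary`, `eff_plantation`,
#'   `eff_secondary`, `rotation`, `secondary_age`, `import_share`,
#'   `export_share`, `construction_share`.
#' @param demand Long tibble `country`, `product`, `year`, `consumption`
#'   (m3 RWE) covering the study years.
#' @param conversion A [conversion_table()].
#' @param half_lives Named list of pool half-lives (see [stand_params()]).
#' @param landfill A [landfill_params()].
#' @param substitution A [substitution_factors()] (its
#'   `construction_share` is overridden per country by the profile
#'   column).
#' @return A validated list of class `world_inputs`.
#' @export
world_inputs <- function(profiles, demand,
                         conversion = conversion_table(),
                         half_lives = list(slash = 10, roots = 10, llp = 35,
                                           slp = 2, landfill = 50),
                         landfill = landfill_params(),
                         substitution = substitution_factors()) {
  need <- c("country", "tropical", "plantation_area_2010", "plant_young",
            "plant_old", "sec_young", "sec_old", "root_shoot_coef",
            "root_shoot_exp", "slash_plantation", "slash_secondary",
            "eff_plantation", "eff_secondary", "rotation", "secondary_age",
            "import_share", "export_share", "construction_share")
  stopifnot(is.data.frame(profiles), is.data.frame(demand))
  miss <- setdiff(need, names(profiles))
  if (length(miss) > 0) {
    abort(paste0("`profiles` is missing columns: ",
                 paste(miss, collapse = ", ")), class = "woodcarbon_error")
  }
  if (!all(c("country", "product", "year", "consumption") %in%
             names(demand))) {
    abort("`demand` needs country, product, year, consumption.",
          class = "woodcarbon_error")
  }
  missing_prof <- setdiff(unique(demand$country), profiles$country)
  if (length(missing_prof) > 0) {
    abort(paste0("No profile for demand countries: ",
                 paste(missing_prof, collapse = ", ")),
          class = "woodcarbon_error")
  }
  structure(list(profiles = tibble::as_tibble(profiles),
                 demand = tibble::as_tibble(demand),
                 conversion = conversion, half_lives = half_lives,
                 landfill = landfill, substitution = substitution),
            class = "world_inputs")
}

# terminal carbon-fate shares of harvested roundwood for one country,
# derived from its base-year production mix
fate_shares <- function(prod_by_product, conversion) {
  rw <- roundwood_from_consumption(prod_by_product, conversion)
  total <- rw$harvest_total
  if (total <= 0) return(product_shares(0.25, 0.25, 0.25, 0.25))
  cons <- setNames(prod_by_product$consumption, prod_by_product$product)
  getc <- function(p) if (p %in% names(cons)) unname(cons[[p]]) else 0
  llp <- getc("llp")
  virgin <- getc("slp") * conversion$pulp_share_virgin
  wfl <- rw$harvest_vslp_wfl
  ind <- total - llp - virgin - wfl
  product_shares(llp / total, virgin / total, wfl / total,
                 max(ind, 0) / total)
}

# per-hectare discounted cost (t CO2e/ha) and product flows for one
# country/forest-type stand under a scenario
stand_pdv_per_ha <- function(prof, type = c("plantation", "secondary",
                                            "secondary_mature",
                                            "new_plantation"),
                             scenario, world, discount, shares) {
  type <- match.arg(type)
  rs <- root_shoot(prof$root_shoot_coef, prof$root_shoot_exp)
  mult <- scenario$plantation_productivity_multiplier
  plant_curve <- fit_monod(prof$plant_young * mult, prof$plant_old * mult)
  sec_curve <- fit_monod(prof$sec_young, prof$sec_old)
  eff_sec <- if (prof$tropical && !is.na(scenario$tropical_efficiency)) {
    scenario$tropical_efficiency
  } else prof$eff_secondary
  N <- discount$N
  if (type %in% c("plantation", "new_plantation")) {
    params <- stand_params(curve = plant_curve, rootshoot = rs,
                           slash_fraction = prof$slash_plantation,
                           shares = shares, half_lives = world$half_lives,
                           rotation = prof$rotation,
                           landfill = world$landfill)
    traj <- simulate_stand(
      params, horizon = N, first_harvest_age = prof$rotation,
      regrow_as = "secondary", efficiency = prof$eff_plantation,
      harvest_years = seq(0, N, by = prof$rotation),
      cf_curve = if (type == "new_plantation") sec_curve else plant_curve,
      cf_start_age = if (type == "new_plantation") 0 else prof$rotation)
  } else {
    age <- prof$secondary_age + if (type == "secondary_mature") 40 else 0
    regrow <- scenario$regrow_secondary_as
    params <- stand_params(curve = sec_curve, rootshoot = rs,
                           slash_fraction = prof$slash_secondary,
                           shares = shares, half_lives = world$half_lives,
                           rotation = prof$rotation,
                           landfill = world$landfill,
                           regrow_curve = plant_curve)
    hy <- if (regrow == "plantation") seq(0, N, by = prof$rotation) else 0L
    traj <- simulate_stand(params, horizon = N, first_harvest_age = age,
                           regrow_as = regrow, efficiency = eff_sec,
                           harvest_years = hy)
  }
  pdv(traj$delta_co2e, discount)
}

#' Allocate national production to plantation and secondary harvests
#'
#' Walks each country's yearly roundwood requirement through the supply
#' hierarchy: existing plantations (sustained yield of the 2010 estate,
#' optionally more productive), then plantations created by the scenario
#' (converted secondary land in scenario 2, new tropical plantings in
#' scenario 4, each becoming harvestable one rotation after creation),
#' then middle-aged (and, in scenario 3, mature) secondary forest for the
#' remainder. Secondary hectares accumulate; repeated plantation harvests
#' of the same hectare count once.
#'
#' @param production Tibble `country`, `year`, `harvest_total`
#'   (m3 roundwood required).
#' @param profiles Country profile tibble (see [world_inputs()]).
#' @param scenario A [scenario_config()].
#' @param conversion A [conversion_table()].
#' @return A tibble, one row per country-year, with harvested volumes and
#'   new clear-cut-equivalent areas by forest type.
#' @export
allocate_supply <- function(production, profiles, scenario,
                            conversion = conversion_table()) {
  stopifnot(is.data.frame(production),
            all(c("country", "year", "harvest_total") %in% names(production)),
            inherits(scenario, "scenario_config"))
  if (!"new_plant_weight" %in% names(profiles)) {
    n_trop <- sum(profiles$tropical)
    profiles$new_plant_weight <-
      ifelse(profiles$tropical, 1 / max(n_trop, 1), 0)
  }
  purrr::map_dfr(split(production, production$country), function(dem) {
    prof <- profiles[profiles$country == dem$country[1], ]
    if (nrow(prof) != 1) {
      abort(paste0("No profile for country ", dem$country[1]),
            class = "woodcarbon_error")
    }
    allocate_country(dem[order(dem$year), ], prof, scenario, conversion)
  })
}

allocate_country <- function(dem, prof, scenario, conversion) {
  mult <- scenario$plantation_productivity_multiplier
  plant_curve <- fit_monod(prof$plant_young * mult, prof$plant_old * mult)
  sec_curve <- fit_monod(prof$sec_young, prof$sec_old)
  rot <- prof$rotation
  eff_sec <- if (prof$tropical && !is.na(scenario$tropical_efficiency)) {
    scenario$tropical_efficiency
  } else prof$eff_secondary

  vol_ha_plant <- carbon_to_volume(
    agb_at_age(plant_curve, rot) * (1 - prof$slash_plantation) *
      prof$eff_plantation, conversion)
  y_mid <- carbon_to_volume(
    agb_at_age(sec_curve, prof$secondary_age) * (1 - prof$slash_secondary) *
      eff_sec, conversion)
  y_mat <- carbon_to_volume(
    agb_at_age(sec_curve, prof$secondary_age + 40) *
      (1 - prof$slash_secondary) * eff_sec, conversion)
  if (vol_ha_plant <= 0 || y_mid <= 0) {
    abort(paste0("Non-positive yield for country ", prof$country,
                 ": demand cannot be met."),
          class = "woodcarbon_infeasible")
  }
  cap_existing <- prof$plantation_area_2010 / rot * vol_ha_plant

  n <- nrow(dem)
  years <- dem$year
  year0 <- years[1]
  rot <- as.integer(round(rot))
  new_plant_rate <- if (prof$tropical) {
    scenario$new_tropical_plantations_ha_yr * prof$new_plant_weight
  } else 0

  vol_plant <- vol_new <- vol_sec_mid <- vol_sec_mat <- numeric(n)
  area_sec_mid <- area_sec_mat <- area_new_used <- area_plant_used <- numeric(n)
  cum_sec_area <- 0        # converted secondary estate (scenario 2)
  cum_sec_hist <- numeric(n)
  max_plant_area <- 0      # peak annual area cut in existing plantations
  max_new_area <- 0

  for (i in seq_len(n)) {
    need <- dem$harvest_total[i]
    t <- years[i]
    # scenario 2: converted secondary land supplies after one rotation
    conv_est <- if (scenario$regrow_secondary_as == "plantation" &&
                    i > rot) cum_sec_hist[i - rot] else 0
    cap_conv <- conv_est / rot * vol_ha_plant
    # scenario 4: new plantings mature after one rotation
    mature_new <- max(0, (t - year0 - rot + 1)) * new_plant_rate
    cap_new <- mature_new / rot * vol_ha_plant

    used_plant <- min(need, cap_existing + cap_conv)
    need <- need - used_plant
    used_new <- min(need, cap_new)
    need <- need - used_new
    vol_plant[i] <- used_plant
    vol_new[i] <- used_new
    area_new_used[i] <- used_new / vol_ha_plant
    if (need > 0) {
      if (scenario$mature_fraction > 0) {
        # equal areas of middle-aged and mature stands
        a <- need / (y_mid + y_mat)
        area_sec_mid[i] <- a
        area_sec_mat[i] <- a
        vol_sec_mid[i] <- a * y_mid
        vol_sec_mat[i] <- a * y_mat
      } else {
        area_sec_mid[i] <- need / y_mid
        vol_sec_mid[i] <- need
      }
    }
    cum_sec_area <- cum_sec_area + area_sec_mid[i] + area_sec_mat[i]
    cum_sec_hist[i] <- cum_sec_area
    existing_share <- if (cap_existing + cap_conv > 0) {
      used_plant * cap_existing / (cap_existing + cap_conv)
    } else 0
    area_plant_used[i] <- existing_share / vol_ha_plant
    max_plant_area <- max(max_plant_area, area_plant_used[i])
    max_new_area <- max(max_new_area, area_new_used[i])
  }

  # distinct-hectare accounting: sustained-yield estate behind peak use,
  # capped by what exists / was planted
  plant_area_once <- min(prof$plantation_area_2010, rot * max_plant_area)
  new_area_once <- min((n - 1) * new_plant_rate, rot * max_new_area)

  tibble::tibble(
    country = prof$country, year = years,
    vol_plantation = vol_plant, vol_new_plantation = vol_new,
    vol_secondary_mid = vol_sec_mid, vol_secondary_mature = vol_sec_mat,
    area_secondary_mid = area_sec_mid, area_secondary_mature = area_sec_mat,
    area_new_plantation_used = area_new_used,
    area_plantation_used = area_plant_used,
    yield_plantation = vol_ha_plant, yield_secondary_mid = y_mid,
    yield_secondary_mature = y_mat,
    plantation_area_once = plant_area_once,
    new_plantation_area_once = new_area_once
  )
}

#' Run one supply scenario end to end
#'
#' Orchestrates the whole pipeline for one scenario: scale demand (wood
#' fuel phase-down in scenario 7), convert consumption to production with
#' fixed trade shares, map production to required roundwood harvest,
#' allocate harvest to forest types and areas, simulate the per-hectare
#' carbon consequences of each forest type, value them as harvest-year
#' equivalent CO2e and aggregate over all harvest years and countries.
#' A second pass holds demand constant at its first-year level to split
#' total costs into a base-demand part and an additional-demand part.
#' Substitution benefits are computed separately and never netted.
#'
#' @param scenario A [scenario_config()] or scenario id 1-7.
#' @param world A [world_inputs()] bundle.
#' @param discount A [discount_spec()].
#' @param study_years Years used to annualize total costs (default 40).
#' @param global_scaling Divide totals by 0.8 (sampled countries produce
#'   80% of world wood)? Default TRUE.
#' @return An object of class `scenario_result`; see [tidy.scenario_result()].
#' @export
run_scenario <- function(scenario, world, discount = discount_spec(),
                         study_years = 40, global_scaling = TRUE) {
  if (is.numeric(scenario)) scenario <- scenario_config(scenario)
  stopifnot(inherits(scenario, "scenario_config"),
            inherits(world, "world_inputs"),
            inherits(discount, "discount_spec"))
  years <- sort(unique(world$demand$year))
  year0 <- years[1]

  demand <- scale_wood_fuel(world$demand, scenario, years)
  base_demand <- world$demand |>
    dplyr::filter(.data$year == year0) |>
    dplyr::select(-"year") |>
    tidyr::crossing(year = years) |>
    dplyr::select("country", "product", "year", "consumption")

  res_total <- scenario_costs(scenario, world, demand, discount)
  res_base <- scenario_costs(scenario, world, base_demand, discount)

  sc <- if (global_scaling) function(x) scale_global(x) else identity
  cost_total <- sc(res_total$pdv_total_co2e)
  cost_base <- sc(res_base$pdv_total_co2e)
  sc_id <- scenario$id
  sc_name <- scenario$name
  summary <- tibble::tibble(
    scenario = sc_id,
    scenario_name = sc_name,
    discount_rate = discount$d,
    horizon = discount$N,
    cost_total_GtCO2e_yr = annualize_co2e(cost_total, study_years),
    cost_2010_demand_GtCO2e_yr = annualize_co2e(cost_base, study_years),
    cost_additional_GtCO2e_yr =
      annualize_co2e(cost_total - cost_base, study_years),
    substitution_GtCO2e_yr =
      annualize_co2e(sc(res_total$substitution_co2e), study_years),
    area_total_Mha = sc(res_total$area_total) / 1e6,
    area_secondary_Mha = sc(res_total$area_secondary) / 1e6,
    area_plantation_Mha = sc(res_total$area_plantation) / 1e6,
    harvest_2010_Mm3 = sc(res_total$harvest_first) / 1e6,
    harvest_2050_Mm3 = sc(res_total$harvest_last) / 1e6
  )
  structure(list(scenario = scenario, discount = discount,
                 summary = summary, ledger = res_total$ledger,
                 plan = res_total$plan, demand = demand),
            class = "scenario_result")
}

# demand-side adjustment for scenario 7: wood fuel declines linearly to
# a fraction of its final-year baseline level
scale_wood_fuel <- function(demand, scenario, years) {
  m50 <- scenario$wood_fuel_multiplier_2050
  if (m50 == 1) return(demand)
  y0 <- min(years); y1 <- max(years)
  demand |>
    dplyr::mutate(mult = ifelse(
      .data$product == "vslp_wfl",
      1 + (m50 - 1) * (.data$year - y0) / (y1 - y0), 1),
      consumption = .data$consumption * .data$mult) |>
    dplyr::select(-"mult")
}

# core costing pass for one demand path
scenario_costs <- function(scenario, world, demand, discount) {
  conv <- world$conversion
  years <- sort(unique(demand$year))
  year0 <- years[1]

  shares <- world$profiles |>
    dplyr::select("country", "import_share", "export_share")
  production <- apply_trade(demand, shares)

  rw <- production |>
    dplyr::select("country", "year", "product",
                  consumption = "production") |>
    roundwood_from_consumption(conv)

  plan <- allocate_supply(rw, world$profiles, scenario, conv)

  # terminal fate shares of harvested carbon, from base-year production
  fates <- production |>
    dplyr::filter(.data$year == year0) |>
    dplyr::select("country", "product", consumption = "production") |>
    (\(d) split(d, d$country))() |>
    purrr::map(fate_shares, conversion = conv)

  ledger <- purrr::map_dfr(split(plan, plan$country), function(pl) {
    prof <- world$profiles[world$profiles$country == pl$country[1], ]
    sh <- fates[[pl$country[1]]]
    p_plant <- stand_pdv_per_ha(prof, "plantation", scenario, world,
                                discount, sh)
    p_mid <- stand_pdv_per_ha(prof, "secondary", scenario, world,
                              discount, sh)
    p_mat <- if (scenario$mature_fraction > 0) {
      stand_pdv_per_ha(prof, "secondary_mature", scenario, world,
                       discount, sh)
    } else NA_real_
    p_new <- if (scenario$new_tropical_plantations_ha_yr > 0 &&
                 prof$tropical) {
      stand_pdv_per_ha(prof, "new_plantation", scenario, world,
                       discount, sh)
    } else NA_real_

    # new plantation-estate hectares enter the ledger the year first cut
    plant_new_area <- diff(c(0, pmin(prof$plantation_area_2010,
                                     prof$rotation *
                                       cummax(pl$area_plantation_used))))
    new_est <- diff(c(0, prof$rotation *
                        cummax(pl$area_new_plantation_used)))
    dplyr::bind_rows(
      tibble::tibble(country = pl$country, year = pl$year,
                     forest_type = "plantation", pdv_per_ha = p_plant,
                     area_ha = plant_new_area),
      tibble::tibble(country = pl$country, year = pl$year,
                     forest_type = "secondary", pdv_per_ha = p_mid,
                     area_ha = pl$area_secondary_mid),
      if (scenario$mature_fraction > 0)
        tibble::tibble(country = pl$country, year = pl$year,
                       forest_type = "secondary", pdv_per_ha = p_mat,
                       area_ha = pl$area_secondary_mature),
      if (!is.na(p_new))
        tibble::tibble(country = pl$country, year = pl$year,
                       forest_type = "plantation", pdv_per_ha = p_new,
                       area_ha = new_est)
    )
  })

  pdv_total <- aggregate_pdv(ledger)

  # substitution: construction wood and wood fuel consumed each year
  subst <- demand |>
    dplyr::left_join(dplyr::select(world$profiles, "country",
                                   "construction_share"),
                     by = "country") |>
    dplyr::mutate(carbon = volume_to_carbon(.data$consumption, conv)) |>
    dplyr::summarise(
      saved_c = sum(ifelse(.data$product == "llp",
                           .data$carbon * .data$construction_share *
                             world$substitution$construction,
                    ifelse(.data$product == "vslp_wfl",
                           .data$carbon * world$substitution$wood_fuel, 0)))
    ) |>
    dplyr::pull("saved_c")

  harvest_by_year <- rw |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(total = sum(.data$harvest_total))

  list(
    pdv_total_co2e = pdv_total,
    substitution_co2e = subst * CO2_PER_C,
    area_secondary = sum(plan$area_secondary_mid) +
      sum(plan$area_secondary_mature),
    area_plantation = sum(plan$plantation_area_once[!duplicated(plan$country)]) +
      sum(plan$new_plantation_area_once[!duplicated(plan$country)]),
    area_total = sum(plan$area_secondary_mid) +
      sum(plan$area_secondary_mature) +
      sum(plan$plantation_area_once[!duplicated(plan$country)]) +
      sum(plan$new_plantation_area_once[!duplicated(plan$country)]),
    harvest_first = harvest_by_year$total[1],
    harvest_last = harvest_by_year$total[nrow(harvest_by_year)],
    ledger = harvest_ledger(ledger),
    plan = plan
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> scenario %d: %s (d = %.0f%%, N = %d)\n",
              x$scenario$id, x$scenario$name, 100 * x$discount$d,
              x$discount$N))
  s <- x$summary
  cat(sprintf("  cost %.3f Gt CO2e/yr (base %.3f + additional %.3f)\n",
              s$cost_total_GtCO2e_yr, s$cost_2010_demand_GtCO2e_yr,
              s$cost_additional_GtCO2e_yr))
  cat(sprintf("  substitution %.3f Gt CO2e/yr; area %.1f Mha\n",
              s$substitution_GtCO2e_yr, s$area_total_Mha))
  invisible(x)
}

#' Tidy a scenario result
#'
#' @param x A `scenario_result` from [run_scenario()].
#' @param ... Unused.
#' @return The one-row summary tibble (costs in Gt CO2e/yr, areas in Mha).
#' @method tidy scenario_result
#' @export
tidy.scenario_result <- function(x, ...) x$summary

#' @method glance scenario_result
#' @export
glance.scenario_result <- function(x, ...) x$summary

#' @method autoplot scenario_result
#' @export
autoplot.scenario_result <- function(object, ...) {
  s <- object$summary |>
    dplyr::select(base = "cost_2010_demand_GtCO2e_yr",
                  additional = "cost_additional_GtCO2e_yr",
                  substitution = "substitution_GtCO2e_yr") |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "component",
                        values_to = "GtCO2e_yr") |>
    dplyr::mutate(GtCO2e_yr = ifelse(.data$component == "substitution",
                                     -.data$GtCO2e_yr, .data$GtCO2e_yr))
  ggplot2::ggplot(s, ggplot2::aes("scenario", .data$GtCO2e_yr,
                                  fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = object$scenario$name, y = "Gt CO2e / yr",
                  fill = NULL,
                  title = "Annualized carbon cost decomposition") +
    ggplot2::theme_minimal()
}
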