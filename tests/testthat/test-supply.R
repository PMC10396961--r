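toy_profiles <- function() {
  tibble::tibble(
    country = c("A", "B"),
    developed = c(TRUE, FALSE),
    tropical = c(FALSE, TRUE),
    plantation_area_2010 = c(1e5, 0),
    plant_young = 6, plant_old = 2.4,
    sec_young = 3, sec_old = 1.2,
    root_shoot_coef = 0.25, root_shoot_exp = 1,
    slash_plantation = 0.2, slash_secondary = 0.3,
    eff_plantation = 1, eff_secondary = c(0.8, 0.5),
    rotation = 10L, secondary_age = 50L,
    import_share = 0, export_share = 0,
    construction_share = 0.5
  )
}

toy_production <- function(total = rep(1e6, 5)) {
  tidyr::crossing(country = c("A", "B"), year = 2010:2014) |>
    dplyr::mutate(harvest_total = rep(total, 2))
}

test_that("clear-cut-equivalent area is volume over yield", {
  expect_equal(clearcut_equivalent_area(1000, 100), 10)
  expect_equal(clearcut_equivalent_area(0, 7), 0)
  expect_error(clearcut_equivalent_area(10, 0), class = "woodcarbon_error")
})

test_that("global scaling divides by the covered share, linearly", {
  expect_equal(scale_global(80), 100)
  expect_equal(scale_global(0), 0)
  a <- 13.7; b <- 29.1
  expect_equal(scale_global(a + b), scale_global(a) + scale_global(b))
  expect_error(scale_global(1, coverage = 0), class = "woodcarbon_error")
})

test_that("secondary yield round-trips with the stand module", {
  prof <- toy_profiles()[2, ]
  plan <- allocate_supply(toy_production(), toy_profiles(),
                          scenario_config(1))
  cv <- fit_monod(prof$sec_young, prof$sec_old)
  carbon <- agb_at_age(cv, prof$secondary_age) *
    (1 - prof$slash_secondary) * prof$eff_secondary
  expect_equal(unique(plan$yield_secondary_mid[plan$country == "B"]),
               carbon_to_volume(carbon), tolerance = 1e-12)
})

test_that("plantations are used first; small demand needs no secondary", {
  profs <- toy_profiles()
  # A has ample plantation capacity for a small demand
  small <- toy_production(rep(1000, 5))
  plan <- allocate_supply(small, profs, scenario_config(1))
  a <- dplyr::filter(plan, country == "A")
  expect_equal(a$area_secondary_mid, rep(0, 5))
  expect_equal(a$vol_plantation, rep(1000, 5))
  # B has no plantations at all
  b <- dplyr::filter(plan, country == "B")
  expect_equal(b$vol_plantation, rep(0, 5))
  expect_equal(b$vol_secondary_mid, rep(1000, 5))
})

test_that("residual secondary area scales linearly with residual demand", {
  profs <- toy_profiles()
  p1 <- allocate_supply(toy_production(rep(5e6, 5)), profs,
                        scenario_config(1))
  cap <- dplyr::filter(p1, country == "A")$vol_plantation[1]
  extra1 <- 5e6 - cap
  p2 <- allocate_supply(toy_production(rep(cap + 2 * extra1, 5)), profs,
                        scenario_config(1))
  a1 <- dplyr::filter(p1, country == "A")$area_secondary_mid[1]
  a2 <- dplyr::filter(p2, country == "A")$area_secondary_mid[1]
  expect_gt(a1, 0)
  expect_equal(a2, 2 * a1, tolerance = 1e-9)
})

test_that("planned volumes meet the production requirement each year", {
  for (sid in c(1, 3, 4)) {
    plan <- allocate_supply(toy_production(), toy_profiles(),
                            scenario_config(sid))
    supplied <- plan$vol_plantation + plan$vol_new_plantation +
      plan$vol_secondary_mid + plan$vol_secondary_mature
    expect_equal(supplied, rep(1e6, 10), tolerance = 1e-9)
  }
})

test_that("mixed mature harvest splits area equally between age classes", {
  plan <- allocate_supply(toy_production(), toy_profiles(),
                          scenario_config(3))
  b <- dplyr::filter(plan, country == "B")
  expect_equal(b$area_secondary_mid, b$area_secondary_mature)
  expect_true(all(b$vol_secondary_mature > b$vol_secondary_mid))
})

test_that("higher plantation productivity cannot increase secondary area", {
  p1 <- allocate_supply(toy_production(), toy_profiles(),
                        scenario_config(1))
  p5 <- allocate_supply(toy_production(), toy_profiles(),
                        scenario_config(5))
  expect_true(all(p5$area_secondary_mid <= p1$area_secondary_mid + 1e-12))
})

test_that("scenario configurations encode their distinguishing assumption", {
  expect_equal(scenario_config(1)$regrow_secondary_as, "secondary")
  expect_equal(scenario_config(2)$regrow_secondary_as, "plantation")
  expect_equal(scenario_config(3)$mature_fraction, 0.5)
  expect_equal(scenario_config(4)$new_tropical_plantations_ha_yr, 2e6)
  expect_equal(scenario_config(5)$plantation_productivity_multiplier, 1.25)
  expect_false(is.na(scenario_config(6)$tropical_efficiency))
  expect_equal(scenario_config(7)$wood_fuel_multiplier_2050, 0.5)
  expect_error(scenario_config(9), class = "woodcarbon_error")
})

test_that("a zero discount rate reports the physical storage change", {
  # per hectare: undiscounted PDV telescopes to the horizon-end CO2e gap
  fx <- gen_stand_fixture()
  tr <- simulate_stand(fx$params, horizon = 40, first_harvest_age = 20,
                       harvest_years = 0L)
  expect_equal(pdv(tr$delta_co2e, discount_spec(0, 40)),
               sum(tr$delta_co2e), tolerance = 1e-12)
  gwp <- fx$params$landfill$gwp100_ch4
  expect_equal(sum(tr$delta_co2e),
               (tr$gap[41] - sum(tr$ch4_c)) * 44 / 12 +
                 sum(tr$ch4_c) * 16 / 12 * gwp,
               tolerance = 1e-9)
  # and the scenario-level ledger holds finite per-hectare values
  w <- get_test_world()
  r <- run_scenario(1, w, discount_spec(0, 40), global_scaling = FALSE)
  expect_true(all(is.finite(r$ledger$pdv_per_ha)))
})

test_that("scenario results expose a tidy one-row summary", {
  w <- get_test_world()
  r <- run_scenario(1, w)
  td <- tidy(r)
  expect_equal(nrow(td), 1)
  expect_true(all(c("cost_total_GtCO2e_yr", "cost_2010_demand_GtCO2e_yr",
                    "cost_additional_GtCO2e_yr", "substitution_GtCO2e_yr",
                    "area_total_Mha") %in% names(td)))
  expect_equal(td$cost_total_GtCO2e_yr,
               td$cost_2010_demand_GtCO2e_yr + td$cost_additional_GtCO2e_yr,
               tolerance = 1e-9)
  p <- autoplot(r)
  expect_s3_class(p, "ggplot")
})
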