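test_that("identical seeds reproduce identical worlds", {
  p1 <- gen_demand_panel(synth_spec(seed = 123))
  p2 <- gen_demand_panel(synth_spec(seed = 123))
  expect_identical(p1, p2)
  w1 <- gen_country_profiles(synth_spec(seed = 123))
  w2 <- gen_country_profiles(synth_spec(seed = 123))
  expect_identical(w1, w2)
  p3 <- gen_demand_panel(synth_spec(seed = 124))
  expect_false(identical(p1$panel$consumption, p3$panel$consumption))
})

test_that("substreams keep generators independent of each other", {
  # profiles must be the same whether or not the panel was drawn first
  spec <- synth_spec(seed = 55)
  gen_demand_panel(spec)
  a <- gen_country_profiles(spec)
  b <- gen_country_profiles(spec)
  expect_identical(a, b)
})

test_that("generated profiles satisfy every downstream invariant", {
  for (seed in seq(1, 981, by = 49)) {
    pr <- gen_country_profiles(synth_spec(seed = seed))
    expect_true(all(pr$plant_young > pr$plant_old))
    expect_true(all(pr$sec_young > pr$sec_old))
    expect_true(all(pr$plant_old > 0 & pr$sec_old > 0))
    expect_true(all(pr$eff_plantation > 0 & pr$eff_plantation <= 1))
    expect_true(all(pr$eff_secondary > 0 & pr$eff_secondary <= 1))
    expect_true(all(pr$slash_plantation >= 0 & pr$slash_plantation <= 1))
    expect_true(all(pr$import_share >= 0 & pr$import_share <= 1))
    es <- sum(pr$export_share)
    expect_true(es == 0 || abs(es - 1) < 1e-9)
    expect_true(all(pr$plantation_area_2010 >= 0))
  }
})

test_that("generated panels sit on the stated generating surface", {
  spec <- synth_spec(seed = 31, noise_sd = 0)
  pan <- gen_demand_panel(spec)
  truth <- pan$truth
  with(pan$panel[pan$panel$product == "llp", ], {
    alpha <- truth$alpha[cbind(match(country, rownames(truth$alpha)), 1)]
    pred <- exp(alpha + truth$beta_pop * log(population) +
                  truth$beta_gdp * log(gdp_pc) +
                  truth$beta_time * pmax(year - 2000, 0))
    expect_equal(consumption, pred, tolerance = 1e-12)
  })
})

test_that("the stand fixture expectations match the simulator exactly", {
  fx <- gen_stand_fixture()
  tr <- simulate_stand(fx$params, horizon = 3,
                       first_harvest_age = fx$first_harvest_age,
                       harvest_years = 0L, efficiency = fx$efficiency)
  expect_equal(as.data.frame(tr[1:3, names(fx$expected)]),
               as.data.frame(fx$expected), tolerance = 1e-12,
               ignore_attr = TRUE)
  # zero-harvest variant gives zero deltas
  tr0 <- simulate_stand(fx$params, horizon = 3,
                        first_harvest_age = fx$first_harvest_age,
                        harvest_years = integer(0))
  expect_equal(tr0$delta, rep(0, 4))
  # all-slash harvest produces no product flows
  p_slash <- stand_params(curve = fx$params$curve,
                          rootshoot = fx$params$rootshoot,
                          slash_fraction = 1,
                          shares = fx$params$shares,
                          half_lives = fx$params$half_lives,
                          rotation = fx$params$rotation)
  tr1 <- simulate_stand(p_slash, horizon = 3, first_harvest_age = 20,
                        harvest_years = 0L, efficiency = 0.5)
  expect_equal(tr1$flow_llp + tr1$flow_slp + tr1$flow_vslp_wfl +
                 tr1$flow_vslp_ind, rep(0, 4))
})

test_that("a generated world drives every scenario without diagnostics", {
  w <- get_test_world()
  expect_s3_class(w$profiles, "tbl_df")
  expect_true(all(c("llp", "slp", "vslp_wfl", "vslp_ind") %in%
                    unique(w$demand$product)))
  expect_true(all(w$demand$consumption > 0))
  expect_no_error(run_scenario(2, w, discount_spec(0.04, 40)))
})
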