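test_that("a noiseless panel is recovered exactly", {
  spec <- synth_spec(seed = 5, n_countries = 6, n_developed = 3,
                     noise_sd = 0)
  pan <- gen_demand_panel(spec)
  for (g in c("developed", "developing")) {
    m <- fit_fe_model(pan$panel, "llp", g, with_time = TRUE)
    expect_equal(m$beta_pop, spec$beta_pop, tolerance = 1e-8)
    expect_equal(m$beta_gdp_pc, spec$beta_gdp, tolerance = 1e-8)
    expect_equal(m$beta_time, spec$beta_time, tolerance = 1e-8)
    expect_equal(m$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("elasticities are recovered within three standard errors", {
  spec <- synth_spec(seed = 17, n_countries = 12, n_developed = 6,
                     noise_sd = 0.3)
  pan <- gen_demand_panel(spec)
  m <- fit_fe_model(pan$panel, "slp", "developing", with_time = TRUE)
  td <- tidy(m)
  se_pop <- td$std.error[td$term == "log(population)"]
  se_gdp <- td$std.error[td$term == "log(gdp_pc)"]
  expect_lt(abs(m$beta_pop - spec$beta_pop), 3 * se_pop)
  expect_lt(abs(m$beta_gdp_pc - spec$beta_gdp), 3 * se_gdp)
  g <- glance(m)
  expect_equal(g$nobs, m$nobs)
  expect_true(g$r.squared > 0 && g$r.squared <= 1)
})

test_that("with one country the fixed effect reduces to plain OLS", {
  # predictors drawn independently so a single country is identified
  set.seed(9)
  n <- 30
  one <- tibble::tibble(
    country = "C01", year = 1991:2020, product = "llp",
    population = exp(rnorm(n, 17, 0.2)),
    gdp_pc = exp(rnorm(n, 9, 0.3)),
    developed = TRUE
  )
  one$consumption <- exp(1 + 0.8 * log(one$population) +
                           0.5 * log(one$gdp_pc) + rnorm(n, 0, 0.2))
  m <- fit_fe_model(one, "llp", "developed", with_time = FALSE)
  ols <- lm(log(consumption) ~ log(population) + log(gdp_pc), data = one)
  expect_equal(m$beta_pop, unname(coef(ols)["log(population)"]),
               tolerance = 1e-10)
  expect_equal(m$beta_gdp_pc, unname(coef(ols)["log(gdp_pc)"]),
               tolerance = 1e-10)
  expect_equal(unname(m$country_intercepts["C01"]),
               unname(coef(ols)["(Intercept)"]), tolerance = 1e-10)
})

test_that("projection anchors to the base year and scales by elasticities", {
  m <- list(beta_pop = 0.8, beta_gdp_pc = 0.5, beta_time = 0,
            with_time = FALSE)
  base <- tibble::tibble(country = "X", consumption = 100,
                         pop_factor = 1, gdp_factor = 1)
  expect_equal(project_consumption(m, base)$consumption_future, 100)

  unit <- list(beta_pop = 1, beta_gdp_pc = 0, with_time = FALSE)
  base2 <- dplyr::mutate(base, pop_factor = 2)
  expect_equal(project_consumption(unit, base2)$consumption_future, 200)

  gdp <- list(beta_pop = 0, beta_gdp_pc = 0.5, with_time = FALSE)
  base3 <- dplyr::mutate(base, gdp_factor = 4)
  expect_equal(project_consumption(gdp, base3)$consumption_future, 200)

  expect_error(project_consumption(m, dplyr::mutate(base, pop_factor = 0)),
               class = "woodcarbon_error")
})

test_that("projection is monotone in growth factors with positive betas", {
  m <- list(beta_pop = 0.8, beta_gdp_pc = 0.5, with_time = FALSE)
  fac <- seq(1, 3, by = 0.25)
  out <- vapply(fac, function(f) {
    project_consumption(
      m, tibble::tibble(country = "X", consumption = 100,
                        pop_factor = f, gdp_factor = 1))$consumption_future
  }, numeric(1))
  expect_true(all(diff(out) > 0))
})

test_that("linear interpolation hits endpoints, midpoint, and series sum", {
  flat <- interpolate_demand(100, 100)
  expect_true(all(flat$consumption == 100))
  ramp <- interpolate_demand(100, 180)
  expect_equal(ramp$consumption[ramp$year == 2010], 100)
  expect_equal(ramp$consumption[ramp$year == 2050], 180)
  expect_equal(ramp$consumption[ramp$year == 2030], 140)
  expect_equal(sum(ramp$consumption), 41 * (100 + 180) / 2)
})

test_that("trade keeps global production equal to global consumption", {
  # no trade: production equals consumption
  cons <- tibble::tibble(country = c("A", "B"), consumption = c(100, 50))
  none <- tibble::tibble(country = c("A", "B"), import_share = 0,
                         export_share = 0)
  expect_equal(apply_trade(cons, none)$production, c(100, 50))

  # two countries: A imports 20% of its consumption, all from B
  shares <- tibble::tibble(country = c("A", "B"),
                           import_share = c(0.2, 0),
                           export_share = c(0, 1))
  out <- apply_trade(cons, shares)
  expect_equal(out$production[out$country == "A"], 80)
  expect_equal(out$production[out$country == "B"], 70)
  expect_equal(sum(out$production), sum(out$consumption))

  # B's production rises by exactly A's import growth
  cons2 <- dplyr::mutate(cons, consumption = c(150, 50))
  out2 <- apply_trade(cons2, shares)
  expect_equal(out2$production[out2$country == "B"] -
                 out$production[out$country == "B"], 0.2 * 50)
})

test_that("trade conservation holds per year and product group", {
  set.seed(21)
  cons <- tidyr::crossing(country = sprintf("C%02d", 1:8),
                          product = c("llp", "slp"),
                          year = 2010:2012) |>
    dplyr::mutate(consumption = runif(dplyr::n(), 10, 100))
  shares <- tibble::tibble(country = sprintf("C%02d", 1:8),
                           import_share = c(rep(0.25, 4), rep(0, 4)),
                           export_share = c(rep(0, 4), rep(0.25, 4)))
  out <- apply_trade(cons, shares)
  bal <- out |>
    dplyr::group_by(product, year) |>
    dplyr::summarise(gap = sum(production) - sum(consumption),
                     .groups = "drop")
  expect_true(all(abs(bal$gap) < 1e-9 * sum(cons$consumption)))
})
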