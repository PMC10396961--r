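#' Specification for the synthetic world generator
#'
#' Controls the synthetic country profiles, demand panels and stand
#' fixtures that make the whole pipeline runnable and testable without
#' any external data. A single root seed fans out to fixed per-table
#' substreams, so adding a generator never perturbs existing outputs and
#' identical seeds give identical worlds.
#'
#' The default world is small but shaped like the real problem: a
#' handful of developed (temperate) and developing (tropical) countries,
#' log-linear demand with country fixed effects and known elasticities,
#' Monod-feasible growth bands (plantations faster than secondary
#' forests, young faster than old), partial plantation coverage so
#' secondary harvest is always needed, and balanced trade.
#'
#' @param seed Integer root seed.
#' @param n_countries Number of countries (default 8).
#' @param n_developed How many are developed/temperate (default 3).
#' @param panel_years Historical panel years (default 1991:2014).
#' @param beta_pop,beta_gdp,beta_time True demand elasticities (defaults
#'   0.8, 0.5, -0.005).
#' @param noise_sd Residual SD of log consumption (default 0.3).
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1, n_countries = 8, n_developed = 3,
                       panel_years = 1991:2014,
                       beta_pop = 0.8, beta_gdp = 0.5, beta_time = -0.005,
                       noise_sd = 0.3) {
  stopifnot(n_countries >= 2, n_developed >= 1, n_developed < n_countries,
            noise_sd >= 0)
  structure(list(seed = as.integer(seed), n_countries = n_countries,
                 n_developed = n_developed, panel_years = panel_years,
                 beta_pop = beta_pop, beta_gdp = beta_gdp,
                 beta_time = beta_time, noise_sd = noise_sd),
            class = "synth_spec")
}

# deterministic substream seed below 2^31
substream <- function(spec, k) {
  (abs(spec$seed) * 7919L + k * 104729L) %% 2147483629L + 1L
}

with_substream <- function(spec, k, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream(spec, k))
  force(code)
}

#' Generate a synthetic consumption panel with known elasticities
#'
#' Draws country population and GDP-per-capita paths and produces
#' log-linear consumption for the three regression-projected product
#' categories with country-product fixed effects, the spec's true
#' elasticities and Gaussian noise. The generating truth is attached so
#' recovery tests can compare fitted coefficients against it.
#'
#' @param spec A [synth_spec()].
#' @return A list with `panel` (tibble: country, year, product,
#'   consumption, gdp_pc, population, developed) and `truth` (the
#'   generating coefficients and fixed effects).
#' @export
gen_demand_panel <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  with_substream(spec, 1L, {
    countries <- sprintf("C%02d", seq_len(spec$n_countries))
    developed <- seq_len(spec$n_countries) <= spec$n_developed
    pop0 <- exp(runif(spec$n_countries, log(2e6), log(2e8)))
    pop_growth <- ifelse(developed, runif(spec$n_countries, 0.000, 0.008),
                         runif(spec$n_countries, 0.008, 0.025))
    gdp0 <- ifelse(developed, runif(spec$n_countries, 2e4, 5e4),
                   runif(spec$n_countries, 1e3, 8e3))
    gdp_growth <- ifelse(developed, runif(spec$n_countries, 0.005, 0.02),
                         runif(spec$n_countries, 0.02, 0.05))
    products <- c("llp", "slp", "vslp_wfl")
    # intercepts chosen so national consumption lands in the tens of
    # millions of m3 and clearly exceeds plantation capacity for most
    # countries, exercising secondary-forest supply
    alpha <- matrix(runif(spec$n_countries * 3, -1, 0.5),
                    nrow = spec$n_countries,
                    dimnames = list(countries, products))
    grid <- tidyr::crossing(country = countries,
                            year = spec$panel_years,
                            product = products) |>
      dplyr::mutate(idx = match(.data$country, countries),
                    population = pop0[.data$idx] *
                      exp(pop_growth[.data$idx] *
                            (.data$year - min(spec$panel_years))),
                    gdp_pc = gdp0[.data$idx] *
                      exp(gdp_growth[.data$idx] *
                            (.data$year - min(spec$panel_years))),
                    developed = developed[.data$idx])
    eps <- rnorm(nrow(grid), 0, spec$noise_sd)
    grid <- grid |>
      dplyr::mutate(
        consumption = exp(
          alpha[cbind(.data$idx, match(.data$product, products))] +
            spec$beta_pop * log(.data$population) +
            spec$beta_gdp * log(.data$gdp_pc) +
            spec$beta_time * pmax(.data$year - 2000, 0) + eps)) |>
      dplyr::select("country", "year", "product", "consumption",
                    "gdp_pc", "population", "developed")
    list(panel = grid,
         truth = list(beta_pop = spec$beta_pop, beta_gdp = spec$beta_gdp,
                      beta_time = spec$beta_time, alpha = alpha,
                      noise_sd = spec$noise_sd))
  })
}

#' Generate internally consistent synthetic country profiles
#'
#' Growth bands are always Monod-feasible (young rate strictly above old
#' rate), harvest efficiencies lie in (0, 1], product shares sum to one,
#' plantation estates cover only part of demand so secondary harvest is
#' exercised, and trade shares balance globally (import shares within
#' countries, export shares summing to one across net exporters).
#'
#' @param spec A [synth_spec()].
#' @return A profile tibble accepted by [world_inputs()].
#' @export
gen_country_profiles <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  with_substream(spec, 2L, {
    n <- spec$n_countries
    countries <- sprintf("C%02d", seq_len(n))
    developed <- seq_len(n) <= spec$n_developed
    tropical <- !developed
    sec_young <- runif(n, 1.5, 4.5)
    sec_old <- sec_young * runif(n, 0.25, 0.6)
    plant_young <- runif(n, 4, 9)
    plant_old <- plant_young * runif(n, 0.3, 0.6)
    exporter <- runif(n) < 0.5
    export_w <- ifelse(exporter, runif(n, 0.2, 1), 0)
    if (sum(export_w) == 0) export_w[1] <- 1
    tibble::tibble(
      country = countries,
      developed = developed,
      tropical = tropical,
      plantation_area_2010 = runif(n, 2e5, 2e6),
      plant_young = plant_young, plant_old = plant_old,
      sec_young = sec_young, sec_old = sec_old,
      root_shoot_coef = 0.489, root_shoot_exp = 0.89,
      slash_plantation = runif(n, 0.15, 0.3),
      slash_secondary = ifelse(tropical, runif(n, 0.3, 0.45),
                               runif(n, 0.2, 0.35)),
      eff_plantation = runif(n, 0.8, 1),
      eff_secondary = ifelse(tropical, runif(n, 0.4, 0.6),
                             runif(n, 0.6, 0.9)),
      rotation = sample(10:20, n, replace = TRUE),
      secondary_age = sample(40:60, n, replace = TRUE),
      import_share = ifelse(exporter, 0, runif(n, 0, 0.3)),
      export_share = export_w / sum(export_w),
      construction_share = runif(n, 0.3, 0.7)
    )
  })
}

#' Generate a full synthetic world bundle
#'
#' Runs the demand pipeline on a generated panel (fit the fixed-effects
#' models per product and development group, project consumption with
#' generated growth factors, interpolate linearly across the study
#' years), derives industrial-fuel demand as a fixed share of the
#' co-product-generating categories, and pairs the demand table with
#' generated country profiles.
#'
#' @param spec A [synth_spec()].
#' @param years Study years (default 2010:2050).
#' @param ind_share VSLP-industrial demand as a share of LLP + SLP
#'   consumption (default 0.15).
#' @return A [world_inputs()] bundle (with the fitted models attached as
#'   attribute `"fe_models"` and the projection table as `"projection"`).
#' @export
gen_world <- function(spec = synth_spec(), years = 2010:2050,
                      ind_share = 0.15) {
  pan <- gen_demand_panel(spec)
  profiles <- gen_country_profiles(spec)
  growth <- with_substream(spec, 3L, {
    tibble::tibble(
      country = profiles$country,
      pop_factor = ifelse(profiles$developed,
                          runif(nrow(profiles), 0.95, 1.2),
                          runif(nrow(profiles), 1.2, 1.8)),
      gdp_factor = ifelse(profiles$developed,
                          runif(nrow(profiles), 1.3, 2),
                          runif(nrow(profiles), 2, 5))
    )
  })
  base <- pan$panel |>
    dplyr::filter(.data$year >= 2006, .data$year <= 2014) |>
    dplyr::group_by(.data$country, .data$product, .data$developed) |>
    dplyr::summarise(consumption = mean(.data$consumption),
                     .groups = "drop")
  models <- list()
  proj <- purrr::map_dfr(c("llp", "slp", "vslp_wfl"), function(p) {
    purrr::map_dfr(c("developed", "developing"), function(g) {
      m <- fit_fe_model(pan$panel, p, g, with_time = TRUE)
      models[[paste(p, g, sep = "_")]] <<- m
      base |>
        dplyr::filter(.data$product == p,
                      .data$developed == (g == "developed")) |>
        dplyr::left_join(growth, by = "country") |>
        project_consumption(model = m, years_elapsed = 40) |>
        dplyr::mutate(product = p)
    })
  })
  demand <- proj |>
    dplyr::rowwise() |>
    dplyr::mutate(series = list(interpolate_demand(
      .data$consumption, .data$consumption_future, years = years))) |>
    dplyr::ungroup() |>
    dplyr::select("country", "product", "series") |>
    tidyr::unnest("series")
  ind <- demand |>
    dplyr::filter(.data$product %in% c("llp", "slp")) |>
    dplyr::group_by(.data$country, .data$year) |>
    dplyr::summarise(consumption = ind_share * sum(.data$consumption),
                     .groups = "drop") |>
    dplyr::mutate(product = "vslp_ind")
  demand <- dplyr::bind_rows(demand, ind) |>
    dplyr::select("country", "product", "year", "consumption") |>
    dplyr::arrange(.data$country, .data$product, .data$year)
  w <- world_inputs(profiles = profiles, demand = demand)
  attr(w, "fe_models") <- models
  attr(w, "projection") <- proj
  attr(w, "spec") <- spec
  w
}

#' Generate a tiny hand-checkable stand fixture
#'
#' Produces integer-friendly stand parameters (a linear root:shoot
#' relation, one-year half-lives for slash, roots and short-lived
#' products) together with a table of expected pool values for the first
#' three simulated years. The expectations are computed here by a
#' straight-line arithmetic calculator that shares no code with
#' [simulate_stand()], so they serve as an independent check on the
#' simulator.
#'
#' @param spec A [synth_spec()] (only the seed substream is used; the
#'   fixture parameters themselves are fixed).
#' @return A list with `params` (a [stand_params()]), `first_harvest_age`,
#'   `efficiency` and `expected` (tibble of pool values for years 0-2).
#' @export
gen_stand_fixture <- function(spec = synth_spec()) {
  curve <- monod_curve(a_max = 200, k_half = 20)
  rs <- root_shoot(coefficient = 0.25, exponent = 1)
  shares <- product_shares(llp = 0.4, slp = 0.2, vslp_wfl = 0.3,
                           vslp_ind = 0.1)
  hl <- list(slash = 1, roots = 1, llp = 2, slp = 1, landfill = 2)
  params <- stand_params(curve = curve, rootshoot = rs,
                         slash_fraction = 0.3, shares = shares,
                         half_lives = hl, rotation = 20,
                         landfill = landfill_params(0.5, 0.5, 28))
  age0 <- 20
  eff <- 1

  # ---- independent straight-line calculation, years 0..2 ----
  agb <- function(a) 200 * a / (20 + a)
  # year 0: harvest at start, no decay of fresh pools, no regrowth
  felled <- agb(age0)                      # 100
  slash0 <- felled * 0.3                   # 30
  roots0 <- 0.25 * felled                  # 25
  llp0 <- felled * 0.7 * 0.4               # 28
  slp0 <- felled * 0.7 * 0.2               # 14
  vslp0 <- felled * 0.7 * 0.4              # 28 burned immediately
  # year 1: decay (half-life 1 -> halves; llp/landfill hl 2 -> *2^-0.5),
  # then regrowth to age 1
  k1 <- 2^(-1 / 2)
  slash1 <- slash0 / 2
  roots1 <- roots0 / 2
  slp1 <- slp0 / 2
  llp1 <- llp0 * k1
  lf1 <- (llp0 - llp1) * 0.5               # half of LLP decay to landfill
  em1 <- slash0 / 2 + roots0 / 2 + slp0 / 2 + (llp0 - llp1) * 0.5
  agb1 <- agb(1)
  # year 2
  slash2 <- slash1 / 2
  roots2 <- roots1 / 2
  slp2 <- slp1 / 2
  llp2 <- llp1 * k1
  lf2 <- lf1 * k1 + (llp1 - llp2) * 0.5
  em2 <- slash1 / 2 + roots1 / 2 + slp1 / 2 + (llp1 - llp2) * 0.5 +
    lf1 * (1 - k1)
  agb2 <- agb(2)
  expected <- tibble::tibble(
    year = 0:2,
    live_agb = c(0, agb1, agb2),
    live_bgb = 0.25 * c(0, agb1, agb2),
    slash = c(slash0, slash1, slash2),
    dead_roots = c(roots0, roots1, roots2),
    llp_stock = c(llp0, llp1, llp2),
    slp_stock = c(slp0, slp1, slp2),
    landfill_stock = c(0, lf1, lf2),
    cumulative_emitted = c(vslp0, vslp0 + em1, vslp0 + em1 + em2)
  )
  list(params = params, first_harvest_age = age0, efficiency = eff,
       expected = expected)
}
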