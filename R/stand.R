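#' One annual first-order decay step
#'
#' Discrete-time decay with exact half-life semantics: after one step a
#' stock is multiplied by `2^(-1 / half_life)`, so after `half_life` annual
#' steps exactly half remains. `half_life = Inf` means no decay.
#'
#' @param stock Carbon stock (tC, vectorised, >= 0).
#' @param half_life Half-life in years (> 0).
#' @return A list with components `remaining` and `released`;
#'   `remaining + released == stock` exactly.
#' @examples
#' decay_step(100, half_life = 1)
#' @export
decay_step <- function(stock, half_life) {
  stopifnot(is.numeric(stock), is.numeric(half_life))
  if (any(stock < 0)) abort("`stock` must be >= 0.",
                            class = "woodcarbon_error")
  if (any(half_life <= 0)) abort("`half_life` must be > 0.",
                                 class = "woodcarbon_error")
  remaining <- stock * 2^(-1 / half_life)
  list(remaining = remaining, released = stock - remaining)
}

#' Per-hectare carbon pool state
#'
#' A snapshot of the carbon pools tracked per hectare: live above- and
#' below-ground biomass, slash (felled wood left on site), dead roots,
#' long- and short-lived product stocks, landfill stock, and the carbon
#' emitted to the atmosphere since simulation start.
#'
#' @param age Stand age (years).
#' @param live_agb,live_bgb,slash,dead_roots,llp_stock,slp_stock,landfill_stock
#'   Carbon stocks (tC/ha, >= 0).
#' @param cumulative_emitted Carbon released since start (tC/ha).
#' @return An object of class `pool_state` (named list).
#' @export
pool_state <- function(age = 0, live_agb = 0, live_bgb = 0, slash = 0,
                       dead_roots = 0, llp_stock = 0, slp_stock = 0,
                       landfill_stock = 0, cumulative_emitted = 0) {
  st <- list(age = age, live_agb = live_agb, live_bgb = live_bgb,
             slash = slash, dead_roots = dead_roots, llp_stock = llp_stock,
             slp_stock = slp_stock, landfill_stock = landfill_stock,
             cumulative_emitted = cumulative_emitted)
  stocks <- unlist(st[-1])
  if (any(stocks < -1e-12)) abort("Pool stocks must be >= 0.",
                                  class = "woodcarbon_error")
  structure(st, class = "pool_state")
}

total_stored <- function(state) {
  state$live_agb + state$live_bgb + state$slash + state$dead_roots +
    state$llp_stock + state$slp_stock + state$landfill_stock
}

#' Stand simulation parameters
#'
#' Bundles everything needed to simulate one hectare: the growth curve the
#' stand (and its no-harvest counterfactual) follows, root:shoot
#' allometry, the slash fraction, product allocation shares, per-pool
#' half-lives, the rotation length, landfill/methane parameters, an
#' optional regrowth curve (when post-harvest regrowth differs from the
#' original stand, e.g. conversion to plantation) and an optional thinning
#' schedule.
#'
#' Half-life defaults (slash 10, dead roots 10, LLP 35, SLP 2,
#' landfill 50 years) are configuration values; set them per country or
#' climate zone when better information is available.
#'
#' @param curve [monod_curve()] of the standing forest.
#' @param rootshoot [root_shoot()] allometry.
#' @param slash_fraction Share of felled above-ground biomass left on site
#'   (in \[0, 1\]).
#' @param shares [product_shares()] for recovered wood.
#' @param half_lives Named list with elements `slash`, `roots`, `llp`,
#'   `slp`, `landfill` (years, > 0; `Inf` allowed).
#' @param rotation Harvest cycle length in years (> 0).
#' @param landfill [landfill_params()].
#' @param regrow_curve Optional [monod_curve()] for post-harvest regrowth;
#'   defaults to `curve`.
#' @param thinning Optional data frame with columns `offset` (years after
#'   the preceding harvest) and `fraction` (share of live AGB removed).
#' @return An object of class `stand_params`.
#' @export
stand_params <- function(curve,
                         rootshoot = root_shoot(),
                         slash_fraction = 0.3,
                         shares = product_shares(0.25, 0.25, 0.25, 0.25),
                         half_lives = list(slash = 10, roots = 10,
                                           llp = 35, slp = 2, landfill = 50),
                         rotation = 20,
                         landfill = landfill_params(),
                         regrow_curve = NULL,
                         thinning = NULL) {
  stopifnot(inherits(curve, "monod_curve"),
            inherits(rootshoot, "root_shoot"),
            inherits(shares, "product_shares"),
            inherits(landfill, "landfill_params"))
  if (slash_fraction < 0 || slash_fraction > 1) {
    abort("`slash_fraction` must be in [0, 1].", class = "woodcarbon_error")
  }
  need <- c("slash", "roots", "llp", "slp", "landfill")
  if (!all(need %in% names(half_lives))) {
    abort(paste0("`half_lives` must name: ", paste(need, collapse = ", ")),
          class = "woodcarbon_error")
  }
  if (any(unlist(half_lives[need]) <= 0)) {
    abort("All half-lives must be > 0.", class = "woodcarbon_error")
  }
  if (rotation <= 0) abort("`rotation` must be > 0.",
                           class = "woodcarbon_error")
  if (!is.null(thinning)) {
    stopifnot(is.data.frame(thinning),
              all(c("offset", "fraction") %in% names(thinning)))
    if (any(thinning$fraction < 0 | thinning$fraction > 1)) {
      abort("Thinning fractions must be in [0, 1].",
            class = "woodcarbon_error")
    }
  }
  structure(list(curve = curve, rootshoot = rootshoot,
                 slash_fraction = slash_fraction, shares = shares,
                 half_lives = half_lives[need], rotation = rotation,
                 landfill = landfill,
                 regrow_curve = regrow_curve %||% curve,
                 thinning = thinning),
            class = "stand_params")
}

#' Clear-cut harvest of a stand
#'
#' Fells all live above-ground biomass. A `slash_fraction` share of felled
#' wood stays on site as slash; of the remainder, `efficiency` is
#' recovered and split into product pools by the allocation shares, and
#' the unrecovered part is also left as slash. All live roots move to the
#' dead-roots pool. Wood allocated to the very-short-lived categories
#' (wood fuel and industrial fuel) is burned and counted as an immediate
#' emission. Carbon is conserved exactly.
#'
#' @param state A [pool_state()].
#' @param params A [stand_params()].
#' @param efficiency Share of felled non-slash wood recovered (0, 1\].
#' @return A list with `state` (the post-harvest [pool_state()]) and
#'   `flows`, a named vector of product carbon flows
#'   (`llp`, `slp`, `vslp_wfl`, `vslp_ind`, `immediate_emission`, tC/ha).
#' @export
harvest_event <- function(state, params, efficiency = 1) {
  stopifnot(inherits(state, "pool_state"), inherits(params, "stand_params"))
  if (efficiency <= 0 || efficiency > 1) {
    abort("`efficiency` must be in (0, 1].", class = "woodcarbon_error")
  }
  felled <- state$live_agb
  sh <- params$shares
  to_slash <- felled * params$slash_fraction +
    felled * (1 - params$slash_fraction) * (1 - efficiency)
  recovered <- felled * (1 - params$slash_fraction) * efficiency
  flows <- c(llp = recovered * sh$llp,
             slp = recovered * sh$slp,
             vslp_wfl = recovered * sh$vslp_wfl,
             vslp_ind = recovered * sh$vslp_ind)
  immediate <- flows[["vslp_wfl"]] + flows[["vslp_ind"]]
  new_state <- pool_state(
    age = 0,
    live_agb = 0,
    live_bgb = 0,
    slash = state$slash + to_slash,
    dead_roots = state$dead_roots + state$live_bgb,
    llp_stock = state$llp_stock + flows[["llp"]],
    slp_stock = state$slp_stock + flows[["slp"]],
    landfill_stock = state$landfill_stock,
    cumulative_emitted = state$cumulative_emitted + immediate
  )
  list(state = new_state,
       flows = c(flows, immediate_emission = immediate))
}

#' Simulate per-hectare carbon pools under harvest and no-harvest paths
#'
#' Runs the annual carbon bookkeeping for one hectare over `horizon`
#' years. The harvest path clear-cuts the stand at the scheduled harvest
#' years (year 0 and every `rotation` years by default), decays slash,
#' dead roots, products and landfill stocks each year, and regrows the
#' live pools along the regrowth curve starting the year after a harvest.
#' The counterfactual path lets the same stand keep growing unharvested.
#'
#' Within a year the order of events is: decay of existing dead and
#' product stocks, then any scheduled harvest (at the start of the year,
#' so freshly created stocks do not decay in the harvest year), then live
#' growth (skipped in a harvest year). Decayed long-lived-product carbon
#' routes partly to the landfill pool; landfill releases split into CO2
#' and CH4.
#'
#' The atmospheric effect of the harvest in year `t` is the first
#' difference of the storage gap (counterfactual total storage minus
#' harvest-path total storage, including the gap's change from zero in
#' year 0); positive values are emissions.
#'
#' @param params A [stand_params()].
#' @param horizon Number of simulated years after the first harvest year
#'   (the output covers years `0..horizon`).
#' @param first_harvest_age Stand age at the first harvest (years).
#' @param regrow_as `"secondary"` (regrow on the stand's own curve),
#'   `"plantation"` (regrow on `params$regrow_curve`) or `"none"` (no
#'   regrowth after harvest).
#' @param efficiency Harvest efficiency passed to [harvest_event()].
#' @param harvest_years Integer years (0-based) at which clear-cuts occur;
#'   default year 0 and every `rotation` years. Use `integer(0)` for a
#'   no-harvest run.
#' @param cf_curve Counterfactual growth curve (default `params$curve`).
#' @param cf_start_age Counterfactual stand age at year 0 (default
#'   `first_harvest_age`).
#' @return A `stand_trajectory`: a tibble with one row per year and
#'   columns for every harvest-path pool, per-year emissions and methane
#'   (`emitted_c`, `ch4_c`), counterfactual biomass (`cf_agb`, `cf_bgb`),
#'   total storages, the storage `gap`, its first difference `delta`
#'   (tC/ha/yr, positive = emission), the methane-weighted `delta_co2e`,
#'   and product carbon flows in harvest years.
#' @export
simulate_stand <- function(params, horizon, first_harvest_age,
                           regrow_as = c("secondary", "plantation", "none"),
                           efficiency = 1,
                           harvest_years = NULL,
                           cf_curve = NULL,
                           cf_start_age = NULL) {
  stopifnot(inherits(params, "stand_params"))
  regrow_as <- match.arg(regrow_as)
  if (horizon < 1) abort("`horizon` must be >= 1.", class = "woodcarbon_error")
  if (first_harvest_age < 0) abort("`first_harvest_age` must be >= 0.",
                                   class = "woodcarbon_error")
  if (is.null(harvest_years)) {
    harvest_years <- if (regrow_as == "none") 0L else
      seq(0L, horizon, by = params$rotation)
  }
  cf_curve <- cf_curve %||% params$curve
  cf_start_age <- cf_start_age %||% first_harvest_age
  hl <- params$half_lives
  lf <- params$landfill
  rs <- params$rootshoot
  grow_curve <- params$curve      # curve the live stand currently follows
  regrow_curve <- switch(regrow_as,
                         secondary = params$curve,
                         plantation = params$regrow_curve,
                         none = NULL)

  agb0 <- agb_at_age(params$curve, first_harvest_age)
  st <- pool_state(age = first_harvest_age, live_agb = agb0,
                   live_bgb = bgb_from_agb(rs, agb0))
  initial_stored <- total_stored(st)
  cf_age <- cf_start_age
  cf_agb <- agb_at_age(cf_curve, cf_age)
  cf_bgb <- bgb_from_agb(rs, cf_agb)
  cf_initial <- cf_agb + cf_bgb
  cum_growth <- 0
  cf_cum_growth <- 0
  last_harvest <- NA_integer_

  n <- horizon + 1L
  out <- tibble::tibble(
    year = 0:horizon,
    age = NA_real_, live_agb = NA_real_, live_bgb = NA_real_,
    slash = NA_real_, dead_roots = NA_real_, llp_stock = NA_real_,
    slp_stock = NA_real_, landfill_stock = NA_real_,
    cumulative_emitted = NA_real_, emitted_c = 0, ch4_c = 0,
    flow_llp = 0, flow_slp = 0, flow_vslp_wfl = 0, flow_vslp_ind = 0,
    cf_agb = NA_real_, cf_bgb = NA_real_,
    stored_harvest = NA_real_, stored_counterfactual = NA_real_,
    growth_input = 0, cf_growth_input = 0
  )

  for (i in seq_len(n)) {
    t <- i - 1L
    emitted <- 0
    ch4 <- 0

    # 1. decay of dead and product pools present at the start of the year
    d_slash <- decay_step(st$slash, hl$slash)
    d_roots <- decay_step(st$dead_roots, hl$roots)
    d_slp <- decay_step(st$slp_stock, hl$slp)
    d_llp <- decay_step(st$llp_stock, hl$llp)
    to_landfill <- d_llp$released * lf$landfill_fraction_of_llp_decay
    d_lf <- decay_step(st$landfill_stock, hl$landfill)
    ch4 <- d_lf$released * lf$methane_fraction
    emitted <- d_slash$released + d_roots$released + d_slp$released +
      (d_llp$released - to_landfill) + d_lf$released
    st <- pool_state(age = st$age, live_agb = st$live_agb,
                     live_bgb = st$live_bgb,
                     slash = d_slash$remaining,
                     dead_roots = d_roots$remaining,
                     llp_stock = d_llp$remaining,
                     slp_stock = d_slp$remaining,
                     landfill_stock = d_lf$remaining + to_landfill,
                     cumulative_emitted = st$cumulative_emitted + emitted)

    # 2. harvest at the start of the year
    harvested <- t %in% harvest_years
    if (harvested) {
      hv <- harvest_event(st, params, efficiency)
      emitted <- emitted + hv$flows[["immediate_emission"]]
      out$flow_llp[i] <- hv$flows[["llp"]]
      out$flow_slp[i] <- hv$flows[["slp"]]
      out$flow_vslp_wfl[i] <- hv$flows[["vslp_wfl"]]
      out$flow_vslp_ind[i] <- hv$flows[["vslp_ind"]]
      st <- hv$state
      last_harvest <- t
      grow_curve <- regrow_curve
    }

    # 3. thinning (relative to the preceding harvest; never in a harvest year)
    if (!harvested && !is.null(params$thinning) && !is.na(last_harvest)) {
      row <- params$thinning[params$thinning$offset == (t - last_harvest), ]
      if (nrow(row) == 1 && st$live_agb > 0) {
        felled <- st$live_agb * row$fraction
        sh <- params$shares
        to_slash <- felled * params$slash_fraction +
          felled * (1 - params$slash_fraction) * (1 - efficiency)
        recovered <- felled * (1 - params$slash_fraction) * efficiency
        new_agb <- st$live_agb - felled
        new_bgb <- bgb_from_agb(rs, new_agb)
        vslp <- recovered * (sh$vslp_wfl + sh$vslp_ind)
        emitted <- emitted + vslp
        out$flow_llp[i] <- out$flow_llp[i] + recovered * sh$llp
        out$flow_slp[i] <- out$flow_slp[i] + recovered * sh$slp
        out$flow_vslp_wfl[i] <- out$flow_vslp_wfl[i] + recovered * sh$vslp_wfl
        out$flow_vslp_ind[i] <- out$flow_vslp_ind[i] + recovered * sh$vslp_ind
        st <- pool_state(age = st$age, live_agb = new_agb, live_bgb = new_bgb,
                         slash = st$slash + to_slash,
                         dead_roots = st$dead_roots + (st$live_bgb - new_bgb),
                         llp_stock = st$llp_stock + recovered * sh$llp,
                         slp_stock = st$slp_stock + recovered * sh$slp,
                         landfill_stock = st$landfill_stock,
                         cumulative_emitted = st$cumulative_emitted + vslp)
      }
    }

    # 4. live growth (regrowth starts the year after a harvest)
    if (!harvested && !is.null(grow_curve)) {
      inc <- agb_at_age(grow_curve, st$age + 1) - agb_at_age(grow_curve, st$age)
      new_agb <- st$live_agb + inc
      new_bgb <- bgb_from_agb(rs, new_agb)
      cum_growth <- cum_growth + inc + (new_bgb - st$live_bgb)
      out$growth_input[i] <- inc + (new_bgb - st$live_bgb)
      st <- pool_state(age = st$age + 1, live_agb = new_agb,
                       live_bgb = new_bgb, slash = st$slash,
                       dead_roots = st$dead_roots, llp_stock = st$llp_stock,
                       slp_stock = st$slp_stock,
                       landfill_stock = st$landfill_stock,
                       cumulative_emitted = st$cumulative_emitted)
    }

    # 5. counterfactual growth
    cf_inc <- agb_at_age(cf_curve, cf_age + 1) - agb_at_age(cf_curve, cf_age)
    cf_age <- cf_age + 1
    cf_agb <- cf_agb + cf_inc
    new_cf_bgb <- bgb_from_agb(rs, cf_agb)
    out$cf_growth_input[i] <- cf_inc + (new_cf_bgb - cf_bgb)
    cf_cum_growth <- cf_cum_growth + cf_inc + (new_cf_bgb - cf_bgb)
    cf_bgb <- new_cf_bgb

    out$age[i] <- st$age
    out$live_agb[i] <- st$live_agb
    out$live_bgb[i] <- st$live_bgb
    out$slash[i] <- st$slash
    out$dead_roots[i] <- st$dead_roots
    out$llp_stock[i] <- st$llp_stock
    out$slp_stock[i] <- st$slp_stock
    out$landfill_stock[i] <- st$landfill_stock
    out$cumulative_emitted[i] <- st$cumulative_emitted
    out$emitted_c[i] <- emitted
    out$ch4_c[i] <- ch4
    out$cf_agb[i] <- cf_agb
    out$cf_bgb[i] <- cf_bgb
    out$stored_harvest[i] <- total_stored(st)
    out$stored_counterfactual[i] <- cf_agb + cf_bgb
  }

  # storage gap relative to the common pre-harvest baseline
  gap <- (out$stored_counterfactual - cf_initial) -
    (out$stored_harvest - initial_stored)
  out$gap <- gap
  out$delta <- c(gap[1], diff(gap))
  out$delta_co2e <- (out$delta - out$ch4_c) * CO2_PER_C +
    out$ch4_c * CH4_PER_C * lf$gwp100_ch4

  attr(out, "params") <- params
  attr(out, "initial_stored") <- initial_stored
  attr(out, "cf_initial") <- cf_initial
  class(out) <- c("stand_trajectory", class(out))
  out
}

#' Annual atmospheric-change series of a trajectory
#'
#' First differences of the storage gap (counterfactual minus harvest-path
#' total storage); positive values are emissions, negative values are
#' removals. The cumulative sum of the series equals the storage gap at
#' any year.
#'
#' @param trajectory A `stand_trajectory` from [simulate_stand()], or any
#'   data frame with a `gap` column.
#' @return Numeric vector, one value per simulated year (tC/ha/yr).
#' @export
annual_atmosphere_delta <- function(trajectory) {
  stopifnot(is.data.frame(trajectory), "gap" %in% names(trajectory))
  g <- trajectory$gap
  c(g[1], diff(g))
}

#' @method autoplot stand_trajectory
#' @export
autoplot.stand_trajectory <- function(object, ...) {
  pools <- object |>
    dplyr::select("year", "live_agb", "live_bgb", "slash", "dead_roots",
                  "llp_stock", "slp_stock", "landfill_stock") |>
    tidyr::pivot_longer(-"year", names_to = "pool", values_to = "carbon")
  totals <- object |>
    dplyr::select("year", harvest = "stored_harvest",
                  counterfactual = "stored_counterfactual") |>
    tidyr::pivot_longer(-"year", names_to = "path", values_to = "carbon")
  ggplot2::ggplot(pools, ggplot2::aes(.data$year, .data$carbon)) +
    ggplot2::geom_area(ggplot2::aes(fill = .data$pool), alpha = 0.85) +
    ggplot2::geom_line(data = totals,
                       ggplot2::aes(linetype = .data$path),
                       linewidth = 0.6) +
    ggplot2::labs(x = "Years since first harvest", y = "Carbon (tC/ha)",
                  fill = "Pool", linetype = "Total stored") +
    ggplot2::theme_minimal()
}
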