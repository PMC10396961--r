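# Independent straight-line calculators used as oracles. These use only
# base-R arithmetic and plain loops -- no calls into the package's
# simulation or valuation code paths.

# Per-hectare harvest-year-equivalent cost (t CO2e/ha) of a stand,
# recomputed cell by cell the way one would in a spreadsheet.
oracle_stand_pdv <- function(a_max, k_half, rs_coef, rs_exp,
                             slash, eff, shares, half_lives,
                             lf_frac, ch4_frac, gwp,
                             age0, N, d, harvest_years = 0) {
  agb <- function(a) a_max * a / (k_half + a)
  bgb <- function(x) rs_coef * x^rs_exp
  keep <- function(h) 2^(-1 / h)

  live_a <- agb(age0); live_b <- bgb(live_a); age <- age0
  sl <- rt <- llp <- slp <- lfl <- 0
  cf_age <- age0; cf_a <- agb(age0); cf_b <- bgb(cf_a)
  init <- live_a + live_b
  cf_init <- cf_a + cf_b
  gap_prev <- 0
  total <- 0

  for (t in 0:N) {
    rel_sl <- sl * (1 - keep(half_lives$slash)); sl <- sl - rel_sl
    rel_rt <- rt * (1 - keep(half_lives$roots)); rt <- rt - rel_rt
    rel_slp <- slp * (1 - keep(half_lives$slp)); slp <- slp - rel_slp
    rel_llp <- llp * (1 - keep(half_lives$llp)); llp <- llp - rel_llp
    to_lf <- rel_llp * lf_frac
    rel_lf <- lfl * (1 - keep(half_lives$landfill))
    lfl <- lfl - rel_lf + to_lf
    ch4 <- rel_lf * ch4_frac
    harvested <- t %in% harvest_years
    if (harvested) {
      felled <- live_a
      sl <- sl + felled * slash + felled * (1 - slash) * (1 - eff)
      recov <- felled * (1 - slash) * eff
      llp <- llp + recov * shares[["llp"]]
      slp <- slp + recov * shares[["slp"]]
      rt <- rt + live_b
      live_a <- 0; live_b <- 0; age <- 0
    } else {
      inc <- agb(age + 1) - agb(age)
      live_a <- live_a + inc
      live_b <- bgb(live_a)
      age <- age + 1
    }
    cf_a <- cf_a + agb(cf_age + 1) - agb(cf_age)
    cf_age <- cf_age + 1
    cf_b <- bgb(cf_a)
    stored <- live_a + live_b + sl + rt + llp + slp + lfl
    gap <- (cf_a + cf_b - cf_init) - (stored - init)
    delta <- gap - gap_prev
    gap_prev <- gap
    co2e <- (delta - ch4) * 44 / 12 + ch4 * (16 / 12) * gwp
    total <- total + co2e / (1 + d)^t
  }
  total
}

# memoised default synthetic world shared across test files
get_test_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- gen_world(synth_spec(seed = 42))
    }
    cache
  }
})
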