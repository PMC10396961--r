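---
title: "Carbon bookkeeping for wood harvest scenarios: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carbon bookkeeping for wood harvest scenarios: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woodcarbon)
library(dplyr)
```

## The accounting problem

Most carbon accounting for wood use nets the emissions of new harvests
against forest growth that would have happened anyway — regrowth from
past harvests, recovery from agricultural abandonment, CO2
fertilisation. That netting makes new harvests look cheap or free.
`woodcarbon` takes the opposite, attributional view: the carbon cost of
a harvest is the difference between the carbon the stand and its
products *would* store if harvested and the carbon the same stand would
store if left alone, tracked year by year, and valued back to the year
of harvest with a discount rate.

The package is a bookkeeping simulator in the stand-level tradition:
carbon moves between pools (live above- and below-ground biomass,
slash, dead roots, long- and short-lived products, landfills, the
atmosphere), every transfer is conserved exactly, and national results
are built by multiplying per-hectare trajectories by harvested areas.

## Stand-level model

### Growth

Live above-ground biomass accumulates along a Monod (saturating
hyperbola) curve,

$$\mathrm{AGB}(a) = \frac{a_{\max}\, a}{k_{1/2} + a},$$

with $a_{\max}$ the asymptotic stock (tC ha^-1^) and $k_{1/2}$ the age
at half saturation (years). Growth-rate inputs usually come as mean
annual increments in two broad age bands (young stands under 20 years,
older stands above). `fit_monod()` finds the curve whose band-mean
increments match both numbers. Matching band means gives a
two-equation, two-unknown system which — conveniently — has a closed
form:

$$k_{1/2} = \frac{2w\,r_{\mathrm{old}}}{r_{\mathrm{young}} -
r_{\mathrm{old}}}, \qquad a_{\max} = r_{\mathrm{young}}\,(k_{1/2} + w),$$

with $w$ the band width (20 years). We use the closed form rather than
a numerical solver: it is exact, it cannot fail to converge, and the
round-trip property (band rates of a fitted curve reproduce the
inputs) holds to machine precision. A fit exists only when the young
rate strictly exceeds the old rate, because Monod increments decline
with age; equal or inverted bands are rejected as infeasible rather
than silently smoothed.

Below-ground biomass follows the standard power-law allometry
$\mathrm{BGB} = c\,\mathrm{AGB}^{e}$. The defaults $c = 0.489$,
$e = 0.89$ are widely used literature values; both are explicit
configuration, not buried constants, because root:shoot ratios vary
substantially across biomes.

### Harvest, decay, and the counterfactual

`simulate_stand()` advances one hectare annually. Within a year the
order is:

1. **Decay** of dead and product pools present at the start of the
   year. Each pool decays at a first-order rate with exact discrete
   half-life semantics: one annual step multiplies a stock by
   $2^{-1/h}$, so after $h$ steps exactly half remains. Decayed
   short-lived products and slash are released as CO2; decayed
   long-lived products route partly (default 50%) to the landfill
   pool; landfill releases split into CO2 and methane (default 50/50),
   with methane weighted by its 100-year global warming potential
   (default 28) when results are expressed in CO2e.
2. **Harvest**, if scheduled, at the start of the year. Clear-cutting
   zeroes the live pools: a `slash_fraction` of felled wood stays on
   site, the unrecovered part of the rest (one minus the harvest
   efficiency) also stays as slash, live roots move to the dead-root
   pool, and recovered wood splits into the four product categories.
   Wood fuel and industrial fuel are burned immediately.
3. **Growth**: the live stand adds one year's Monod increment; a
   freshly cut stand stays bare until the following year, which
   reproduces the expected phasing (large emission in the harvest
   year, continued decay emissions in the next, net removals late in
   the cycle as regrowth accelerates).

Running decay before the harvest event means freshly created stocks do
not decay in their first year while stocks from earlier harvests keep
decaying continuously — the only ordering that satisfies both
properties.

The counterfactual path is the same stand left unharvested, growing
along its own curve. The atmospheric effect of harvest in year $t$ is
the first difference of the storage gap (counterfactual minus
harvest-path total storage, both measured from their own year-0
baselines); positive values are emissions. Measuring each path from
its own baseline keeps the no-harvest case identically zero and lets
scenario 4 pair a plantation with a bare-land secondary-regrowth
counterfactual without inventing pre-study growth.

Per-year carbon closure — stored carbon plus cumulative emissions
minus cumulative growth equals the initial stock — is enforced by
construction and tested to 10^-9^ tC ha^-1^ over 200-year horizons
under random parameters.

Default half-lives (slash 10, dead roots 10, long-lived products 35,
paper 2, landfill 50 years) are mid-range literature values and are
deliberately plain configuration: country- or climate-specific values
drop in through `stand_params()`.

### Valuation

Annual changes are valued as harvest-year-equivalent emissions:

$$\mathrm{PDV}_h = \sum_{t=0}^{N} \frac{\Delta C_{\mathrm{change},t}}{(1+d)^t},$$

with discount rate $d$ (default 4% yr^-1^) and horizon $N$ (default 40
years; 100 supported). At $d = 0$ this telescopes to the physical
storage change at the horizon. Series shorter than $N$ are zero-padded
— no regrowth is extrapolated beyond what was simulated, which is the
conservative and reproducible choice. National totals multiply each
year's per-hectare PDV by the new area of that forest type harvested
that year and sum over years and types; annualized results divide the
total by the 40-year study span and convert tC to CO2e with 44/12.

Substitution benefits — avoided production emissions when wood
replaces concrete and steel (1.2 tC saved per tC of construction wood)
or propane (0.175 tC per tC of wood fuel) — are computed separately
and never netted against biogenic costs: substitution lowers the
emissions of the *alternative*, not the absolute emissions of harvest.

## Demand projection

National consumption of long-lived products, paper, and wood fuel is
modelled with a log-transformed fixed-effects panel regression:

$$\log C_{it} = \alpha_i + \beta_p \log \mathrm{pop}_{it} +
\beta_g \log \mathrm{gdppc}_{it} + \beta_\tau\, \tau_t + \varepsilon_{it},$$

where $\tau_t = \max(\mathrm{year} - 2000, 0)$ proxies technology and
policy shifts since 2000 (the coding of "years after 2000" is our
choice; a shifted linear trend behaves identically for projection).
Countries are split into developed and developing groups before
fitting — pooling them overstates future consumption of high-income
countries — and each product is fitted with and without the time
term, giving twelve variants. Fitting uses `stats::lm` with country
dummies, which is numerically identical to the within estimator at
these panel sizes. With a single country the fixed effect collapses to
the intercept.

Projection anchors each country at its base-year consumption (the
2006–2014 mean) and applies the elasticities to exogenous population
and GDP growth factors; demand between the anchor years is linear.
Industrial fuel is not regression-projected: by definition it is
manufacturing waste, so it is derived from the co-product losses of
the other categories. Zero or missing consumption-years are dropped
before the log transform.

Trade keeps its base-year structure: each country's net-import share
of consumption is fixed, exporters hold fixed shares of global
exports, and exports scale so global production equals global
consumption exactly.

## Supply scenarios

Wood demand is met plantation-first: the 2010 plantation estate
supplies its sustained yield (estate / rotation hectares cut per year
at rotation-age yield), and middle-aged secondary forest covers the
remainder at its age-specific yield. Secondary hectares accumulate;
repeated plantation harvests of one hectare count once, implemented as
the sustained-yield estate behind the peak annual harvest
(rotation × peak annual area, capped at the estate that exists).

The seven scenarios modify this template exactly as described in
`?scenario_config`. Three details are package design choices, since the
scheduling is genuinely open:

* **Scenario 2** (conversion): harvested secondary stands enter the
  plantation rotation immediately in the carbon simulation, and the
  converted estate begins supplying wood one rotation after
  conversion. Their area is counted once, at conversion.
* **Scenario 4** (new tropical plantations): 2 Mha yr^-1^ of planting
  is split equally among tropical countries; planted land becomes
  harvestable one rotation after planting; its counterfactual is
  secondary regrowth from bare land.
* **Scenario 7** (wood-fuel reduction): the multiplier on wood-fuel
  consumption falls linearly from 1 in 2010 to 0.5 in 2050.

Within a country, secondary harvest always draws stands at the
configured middle age — there is no explicit age-class inventory, so
results should be read as clear-cut equivalents at stated yields, not
as a forest-estate simulation.

Because national parameters are only reliable for large producers, the
intended workflow covers the 30 countries producing 80% of the world's
wood and scales additive totals by 1/0.8 (`scale_global()`).

## The synthetic world

`gen_world()` produces a complete, internally consistent input bundle
so the entire pipeline runs and tests with no download: log-linear
demand panels with known elasticities ($\beta_p = 0.8$,
$\beta_g = 0.5$, $\beta_\tau = -0.005$, residual SD 0.3 — values in
the range panel studies of wood demand report), Monod-feasible growth
bands (secondary 1.5–4.5 tC ha^-1^ yr^-1^ young-band, plantations
4–9), slash fractions of 0.15–0.45 (higher in the tropics), secondary
harvest efficiencies of 0.4–0.9 (lower in the tropics), rotations of
10–20 years, and plantation estates deliberately too small for
demand, so secondary supply and every scenario lever are exercised.
A single root seed fans out into fixed substreams per table, so
generating one table never perturbs another and identical seeds give
byte-identical worlds.

What the generator does *not* emulate: FAOSTAT's reporting noise and
unit inconsistencies, price responses, real trade topology, or real
national parameter correlations. Passing tests on this world
demonstrate that the bookkeeping, valuation, regression and
allocation machinery is correct and internally consistent — not that
any particular real-world headline number is reproduced. Reproducing
published global figures requires the real country tables (FAOSTAT
consumption and trade, World Bank socioeconomics, national growth and
slash parameters), which drop in through `read_profiles()` /
`read_demand()` in the same CSV layouts.

The default test and acceptance problem sizes — eight countries,
panels over 1991–2014, study years 2010–2050, 100-seed property
sweeps, 200-year closure horizons — were chosen as the smallest sizes
at which every mechanism (trade, both forest types, all seven
scenarios, methane accounting) is active with comfortable margin.

## Numerical choices and degenerate inputs

* Decay uses retention $2^{-1/h}$, which makes "half-life" exact in
  discrete time; `Inf` half-lives are legal and mean no decay.
* Closure is asserted at 10^-9^ tC ha^-1^; product shares must sum to
  one within 10^-9^.
* Harvesting a bare stand is a no-op apart from the age reset; zero
  areas, zero volumes and zero stocks propagate as exact zeros.
* Infeasible inputs fail fast with classed, named errors
  (`woodcarbon_infeasible`, `woodcarbon_validation`) naming the file,
  column and row where applicable — never silent clipping.
* All stochastic code flows through explicit integer seeds; substream
  seeds stay below 2^31.

## A worked stand example

```{r stand-example}
fx <- gen_stand_fixture()
tr <- simulate_stand(fx$params, horizon = 40, first_harvest_age = 20,
                     harvest_years = 0L)
head(tr[, c("year", "live_agb", "slash", "llp_stock",
            "landfill_stock", "gap", "delta")], 4)
pdv(tr$delta, discount_spec(0.04, 40))      # tC/ha, harvest-year equivalent
pdv(tr$delta_co2e, discount_spec(0.04, 40)) # t CO2e/ha, methane-weighted
```

## Known limitations

* Soil carbon is excluded on both paths; published meta-analyses
  suggest harvest losses there, so costs are, if anything,
  understated.
* No biophysical (albedo, cloud) effects, no road-building or other
  indirect effects, no price-mediated market feedbacks or leakage:
  the counterfactual is a forest evolving free of direct human
  activity, not an economic equilibrium.
* Primary-forest harvest is not modelled; all harvested forests are
  assumed secondary or plantation, an optimistic assumption since
  primary forests are more carbon-dense.
* Production (fossil) emissions of harvesting and milling are not
  counted; substitution values are reported but, deliberately, never
  netted.
* The per-country middle-age assumption replaces age-class inventory
  dynamics; long simulations re-harvesting the same secondary land
  are outside the model's intent.
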