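#' Monod biomass-accumulation curve
#'
#' Forest inventories commonly report mean annual above-ground carbon
#' increments in broad age bands (young stands below about 20 years and
#' older stands above). For year-by-year carbon bookkeeping a continuous
#' accumulation curve is needed; a Monod (saturating hyperbola) curve
#' `agb(age) = a_max * age / (k_half + age)` is a standard proxy for stand
#' biomass accumulation.
#'
#' @param a_max Asymptotic above-ground biomass (tC/ha), > 0.
#' @param k_half Age at which biomass reaches `a_max / 2` (years), > 0.
#' @return An object of class `monod_curve`.
#' @examples
#' cv <- monod_curve(a_max = 200, k_half = 20)
#' agb_at_age(cv, c(0, 20, 40))
#' @export
monod_curve <- function(a_max, k_half) {
  stopifnot(is.numeric(a_max), length(a_max) == 1, is.finite(a_max),
            is.numeric(k_half), length(k_half) == 1, is.finite(k_half))
  if (a_max <= 0) abort("`a_max` must be > 0.", class = "woodcarbon_error")
  if (k_half <= 0) abort("`k_half` must be > 0.", class = "woodcarbon_error")
  structure(list(a_max = a_max, k_half = k_half), class = "monod_curve")
}

#' @export
print.monod_curve <- function(x, ...) {
  cat(sprintf("<monod_curve> a_max = %.4g tC/ha, k_half = %.4g yr\n",
              x$a_max, x$k_half))
  invisible(x)
}

#' Above-ground biomass at a given stand age
#'
#' Evaluates the Monod accumulation curve. The curve passes through zero at
#' age 0, reaches half its asymptote at `k_half`, and is strictly
#' increasing and concave.
#'
#' @param curve A [monod_curve()].
#' @param age Stand age in years (vectorised, all >= 0).
#' @return Above-ground biomass (tC/ha), same length as `age`.
#' @export
agb_at_age <- function(curve, age) {
  stopifnot(inherits(curve, "monod_curve"), is.numeric(age))
  if (any(age < 0)) abort("`age` must be >= 0.", class = "woodcarbon_error")
  curve$a_max * age / (curve$k_half + age)
}

#' Fit a Monod curve to banded growth rates
#'
#' Given mean annual above-ground carbon increments for two consecutive age
#' bands (by default ages (0, 20] and (20, 40]), finds the Monod curve whose
#' mean annual increment over each band equals the reported rate. The
#' two-equation system has a closed-form solution:
#' `k_half = 2 * band_width * old / (young - old)` and
#' `a_max = young * (k_half + band_width)`, which this function uses; the
#' band rates are reproduced to machine precision.
#'
#' Because Monod increments strictly decline with age, a fit exists only
#' when `young_rate > old_rate > 0`.
#'
#' @param young_rate Mean annual increment for ages below `band_width`
#'   (tC/ha/yr).
#' @param old_rate Mean annual increment for the next band (tC/ha/yr).
#' @param band_width Band width in years (default 20).
#' @return A [monod_curve()].
#' @examples
#' fit_monod(young_rate = 5, old_rate = 5 / 3, band_width = 20)
#' @export
fit_monod <- function(young_rate, old_rate, band_width = 20) {
  stopifnot(is.numeric(young_rate), is.numeric(old_rate),
            is.numeric(band_width), band_width > 0)
  young_rate <- unname(young_rate)
  old_rate <- unname(old_rate)
  if (!(young_rate > 0 && old_rate > 0)) {
    abort("Band growth rates must be > 0.", class = "woodcarbon_error")
  }
  if (young_rate <= old_rate) {
    abort(
      paste0("No Monod curve fits `young_rate` <= `old_rate` (",
             young_rate, " <= ", old_rate,
             "): mean annual increments must decline with age."),
      class = "woodcarbon_infeasible"
    )
  }
  k_half <- 2 * band_width * old_rate / (young_rate - old_rate)
  a_max <- young_rate * (k_half + band_width)
  monod_curve(a_max = a_max, k_half = k_half)
}

#' Band-mean annual increments implied by a Monod curve
#'
#' The inverse of [fit_monod()]: the mean annual above-ground increment of
#' `curve` over ages `(0, band_width]` and `(band_width, 2 * band_width]`.
#'
#' @inheritParams agb_at_age
#' @param band_width Band width in years (default 20).
#' @return A named numeric vector `c(young_rate, old_rate)`.
#' @export
band_rates <- function(curve, band_width = 20) {
  a1 <- agb_at_age(curve, band_width)
  a2 <- agb_at_age(curve, 2 * band_width)
  c(young_rate = a1 / band_width, old_rate = (a2 - a1) / band_width)
}

#' Root:shoot allometry parameters
#'
#' Below-ground biomass is related to above-ground biomass with the widely
#' used power function `bgb = coefficient * agb^exponent`. The defaults
#' (0.489, 0.89) are standard literature values for forest root:shoot
#' allometry; both are configuration values and should be set per forest
#' type when better information is available.
#'
#' @param coefficient Dimensionless multiplier, > 0.
#' @param exponent Dimensionless power, > 0.
#' @return An object of class `root_shoot`.
#' @export
root_shoot <- function(coefficient = 0.489, exponent = 0.89) {
  stopifnot(is.numeric(coefficient), is.numeric(exponent))
  if (coefficient <= 0 || exponent <= 0) {
    abort("Root:shoot `coefficient` and `exponent` must be > 0.",
          class = "woodcarbon_error")
  }
  structure(list(coefficient = coefficient, exponent = exponent),
            class = "root_shoot")
}

#' Below-ground biomass from above-ground biomass
#'
#' @param params A [root_shoot()] parameter set.
#' @param agb Above-ground biomass (tC/ha), vectorised, all >= 0.
#' @return Below-ground biomass (tC/ha).
#' @examples
#' bgb_from_agb(root_shoot(0.5, 1), 10)
#' @export
bgb_from_agb <- function(params, agb) {
  stopifnot(inherits(params, "root_shoot"), is.numeric(agb))
  if (any(agb < 0)) abort("`agb` must be >= 0.", class = "woodcarbon_error")
  params$coefficient * agb^params$exponent
}
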