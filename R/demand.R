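#' Fit a log-transformed fixed-effects wood-demand model
#'
#' National consumption of a wood-product category is modelled as
#' log-linear in population and GDP per capita with country fixed effects
#' and, optionally, a linear time trend in years after 2000 (a proxy for
#' technological and policy change):
#' `log(C_it) = alpha_i + b_pop log(pop_it) + b_gdp log(gdp_it) +
#' b_time max(year - 2000, 0) + e_it`.
#' Countries are fitted separately for the developed and developing
#' groups, giving twelve model variants over three projected product
#' categories, two groups and two formulae.
#'
#' Rows with non-positive or missing consumption are dropped before the
#' log transform.
#'
#' @param panel A data frame with columns `country`, `year`, `product`,
#'   `consumption` (m3 RWE), `gdp_pc`, `population`, `developed`
#'   (logical).
#' @param product One of `"llp"`, `"slp"`, `"vslp_wfl"`.
#' @param group `"developed"` or `"developing"`.
#' @param with_time Include the years-after-2000 trend term?
#' @return An object of class `fe_model` with elements `beta_pop`,
#'   `beta_gdp_pc`, `beta_time` (NA when `with_time = FALSE`),
#'   `country_intercepts` (named vector), `r_squared`, `sigma`, `nobs`,
#'   plus the fitted [stats::lm] object in `$fit`.
#' @export
fit_fe_model <- function(panel, product, group = c("developed", "developing"),
                         with_time = TRUE) {
  stopifnot(is.data.frame(panel))
  need <- c("country", "year", "product", "consumption", "gdp_pc",
            "population", "developed")
  if (!all(need %in% names(panel))) {
    abort(paste0("Panel needs columns: ", paste(need, collapse = ", ")),
          class = "woodcarbon_error")
  }
  group <- match.arg(group)
  dat <- panel |>
    dplyr::filter(.data$product == !!product,
                  .data$developed == (group == "developed"),
                  !is.na(.data$consumption), .data$consumption > 0,
                  .data$gdp_pc > 0, .data$population > 0) |>
    dplyr::mutate(time_after_2000 = pmax(.data$year - 2000, 0))
  n_ctry <- dplyr::n_distinct(dat$country)
  if (n_ctry < 1 || nrow(dat) < 4) {
    abort("Insufficient data to fit the fixed-effects model.",
          class = "woodcarbon_error")
  }
  # with one country the fixed effect is the plain intercept
  fe_term <- if (n_ctry > 1) "0 + factor(country)" else "1"
  rhs <- paste(c(fe_term, "log(population)", "log(gdp_pc)",
                 if (with_time) "time_after_2000"), collapse = " + ")
  fml <- stats::as.formula(paste("log(consumption) ~", rhs))
  fit <- lm(fml, data = dat)
  if (anyNA(coef(fit))) {
    abort("Singular design: fixed-effects model is not identified.",
          class = "woodcarbon_error")
  }
  cf <- coef(fit)
  if (n_ctry > 1) {
    fe_idx <- grepl("^factor\\(country\\)", names(cf))
    intercepts <- setNames(cf[fe_idx],
                           sub("^factor\\(country\\)", "", names(cf)[fe_idx]))
  } else {
    intercepts <- setNames(cf[["(Intercept)"]], unique(dat$country))
  }
  y <- log(dat$consumption)
  r2 <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(
    product = product, group = group, with_time = with_time,
    beta_pop = unname(cf[["log(population)"]]),
    beta_gdp_pc = unname(cf[["log(gdp_pc)"]]),
    beta_time = if (with_time) unname(cf[["time_after_2000"]]) else NA_real_,
    country_intercepts = intercepts,
    r_squared = r2,
    sigma = sqrt(sum(residuals(fit)^2) / fit$df.residual),
    nobs = nrow(dat),
    fit = fit
  ), class = "fe_model")
}

#' @export
print.fe_model <- function(x, ...) {
  cat(sprintf(
    "<fe_model> %s / %s%s: beta_pop = %.3f, beta_gdp_pc = %.3f%s\n",
    x$product, x$group, if (x$with_time) " (+time)" else "",
    x$beta_pop, x$beta_gdp_pc,
    if (x$with_time) sprintf(", beta_time = %.4f", x$beta_time) else ""))
  cat(sprintf("  %d countries, %d obs, R2 = %.3f, sigma = %.3f\n",
              length(x$country_intercepts), x$nobs, x$r_squared, x$sigma))
  invisible(x)
}

#' @method tidy fe_model
#' @export
tidy.fe_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  keep <- !grepl("^factor\\(country\\)|^\\(Intercept\\)", rownames(s))
  tibble::tibble(
    term = rownames(s)[keep],
    estimate = s[keep, "Estimate"],
    std.error = s[keep, "Std. Error"],
    statistic = s[keep, "t value"],
    p.value = s[keep, "Pr(>|t|)"]
  )
}

#' @method glance fe_model
#' @export
glance.fe_model <- function(x, ...) {
  tibble::tibble(product = x$product, group = x$group,
                 with_time = x$with_time, r.squared = x$r_squared,
                 sigma = x$sigma, nobs = x$nobs,
                 n_countries = length(x$country_intercepts))
}

#' Project consumption to a future year from elasticities
#'
#' Anchors each country at its base-year consumption and scales it by the
#' fitted elasticities applied to exogenous growth factors:
#' `C_future = C_base * pop_factor^beta_pop * gdp_factor^beta_gdp_pc *
#' exp(beta_time * years_elapsed)` (the time term only for with-time
#' models).
#'
#' @param model An `fe_model` (or a list with `beta_pop`, `beta_gdp_pc`,
#'   `beta_time`, `with_time`).
#' @param base A data frame with columns `country`, `consumption`
#'   (base-year level, m3 RWE), `pop_factor` and `gdp_factor` (future /
#'   base ratios, > 0).
#' @param years_elapsed Years between base and target year (default 40).
#' @return `base` with an added `consumption_future` column.
#' @export
project_consumption <- function(model, base, years_elapsed = 40) {
  need <- c("country", "consumption", "pop_factor", "gdp_factor")
  stopifnot(is.data.frame(base))
  if (!all(need %in% names(base))) {
    abort(paste0("`base` needs columns: ", paste(need, collapse = ", ")),
          class = "woodcarbon_error")
  }
  if (any(base$consumption < 0) ||
      any(base$pop_factor <= 0) || any(base$gdp_factor <= 0)) {
    abort("Base consumption must be >= 0 and growth factors > 0.",
          class = "woodcarbon_error")
  }
  time_term <- if (isTRUE(model$with_time)) {
    exp(model$beta_time * years_elapsed)
  } else 1
  base |>
    dplyr::mutate(consumption_future = .data$consumption *
                    .data$pop_factor^model$beta_pop *
                    .data$gdp_factor^model$beta_gdp_pc * time_term) |>
    tibble::as_tibble()
}

#' Linear interpolation of demand between two anchor years
#'
#' Consumption is assumed to grow linearly between the base and target
#' years; endpoints are reproduced exactly.
#'
#' @param c_start,c_end Consumption at the anchor years (>= 0,
#'   vectorised together).
#' @param years Vector of calendar years to evaluate (default 2010:2050).
#' @param year_start,year_end Anchor years (defaults 2010 and 2050).
#' @return A tibble with columns `year` and `consumption` (for scalar
#'   inputs), or a matrix-free long tibble with one row per year per
#'   element.
#' @export
interpolate_demand <- function(c_start, c_end, years = 2010:2050,
                               year_start = 2010, year_end = 2050) {
  if (any(c_start < 0) || any(c_end < 0)) {
    abort("Consumption must be >= 0.", class = "woodcarbon_error")
  }
  stopifnot(length(c_start) == length(c_end), year_end > year_start)
  frac <- (years - year_start) / (year_end - year_start)
  purrr::map2_dfr(c_start, c_end, function(a, b) {
    tibble::tibble(year = years, consumption = a + (b - a) * frac)
  }, .id = if (length(c_start) > 1) "series" else NULL)
}

#' Convert national consumption to national production via fixed trade shares
#'
#' Future trade keeps the base-year structure: within each country the
#' share of consumption supplied by net imports stays fixed, and each net
#' exporter supplies a fixed share of aggregate global exports. Exports
#' are scaled so that global production equals global consumption.
#'
#' @param consumption A data frame with columns `country` and
#'   `consumption` (plus any grouping columns such as `year` or
#'   `product`, within which the balance is computed).
#' @param trade_shares A data frame with columns `country`,
#'   `import_share` (net imports / consumption, in \[0, 1\]) and
#'   `export_share` (share of global exports, summing to 1 across net
#'   exporters; 0 for importers).
#' @return `consumption` with added columns `net_imports` and
#'   `production`; within each group, `sum(production) ==
#'   sum(consumption)`.
#' @export
apply_trade <- function(consumption, trade_shares) {
  stopifnot(is.data.frame(consumption), is.data.frame(trade_shares),
            all(c("country", "consumption") %in% names(consumption)),
            all(c("country", "import_share", "export_share") %in%
                  names(trade_shares)))
  if (any(trade_shares$import_share < 0 | trade_shares$import_share > 1)) {
    abort("`import_share` must be in [0, 1].", class = "woodcarbon_error")
  }
  es <- sum(trade_shares$export_share)
  if (es > 0 && abs(es - 1) > 1e-6) {
    abort("`export_share` must sum to 1 across exporters (or all be 0).",
          class = "woodcarbon_error")
  }
  missing <- setdiff(unique(consumption$country), trade_shares$country)
  if (length(missing) > 0) {
    abort(paste0("No trade shares for: ", paste(missing, collapse = ", ")),
          class = "woodcarbon_error")
  }
  keys <- setdiff(names(consumption), c("country", "consumption"))
  consumption |>
    dplyr::left_join(trade_shares, by = "country") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(
      net_imports = .data$import_share * .data$consumption,
      exports = .data$export_share * sum(.data$net_imports),
      production = .data$consumption - .data$net_imports + .data$exports
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"import_share", -"export_share", -"exports") |>
    tibble::as_tibble()
}
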