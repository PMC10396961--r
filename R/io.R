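#' Read and validate a country profile table
#'
#' Profiles are UTF-8 CSV with a header row and '.' decimals. Validation
#' errors name the file, column and first offending row.
#'
#' @param path CSV path.
#' @return A validated profile tibble (see [world_inputs()] for columns).
#' @export
read_profiles <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  validate_profiles(x, source = path)
}

validate_profiles <- function(x, source = "<profiles>") {
  fail <- function(col, rows, why) {
    abort(sprintf("%s: column `%s`, row(s) %s: %s", source, col,
                  paste(head(rows, 5), collapse = ", "), why),
          class = "woodcarbon_validation")
  }
  chk <- function(col, ok, why) {
    if (!col %in% names(x)) {
      abort(sprintf("%s: missing column `%s`", source, col),
            class = "woodcarbon_validation")
    }
    bad <- which(!ok(x[[col]]))
    if (length(bad) > 0) fail(col, bad, why)
  }
  chk("country", function(v) !is.na(v) & nzchar(v), "must be non-empty")
  chk("plantation_area_2010", function(v) v >= 0, "area must be >= 0")
  for (col in c("plant_young", "plant_old", "sec_young", "sec_old")) {
    chk(col, function(v) v > 0, "growth rates must be > 0")
  }
  bad <- which(!(x$plant_young > x$plant_old))
  if (length(bad) > 0) fail("plant_young", bad,
                            "young-band rate must exceed old-band rate")
  bad <- which(!(x$sec_young > x$sec_old))
  if (length(bad) > 0) fail("sec_young", bad,
                            "young-band rate must exceed old-band rate")
  for (col in c("slash_plantation", "slash_secondary", "import_share",
                "construction_share")) {
    chk(col, function(v) v >= 0 & v <= 1, "must be a fraction in [0, 1]")
  }
  for (col in c("eff_plantation", "eff_secondary")) {
    chk(col, function(v) v > 0 & v <= 1, "must be in (0, 1]")
  }
  chk("rotation", function(v) v > 0, "rotation must be > 0")
  chk("secondary_age", function(v) v > 0, "must be > 0")
  es <- sum(x$export_share)
  if (es > 0 && abs(es - 1) > 1e-6) {
    abort(sprintf("%s: column `export_share` sums to %.6f, must be 1 (or 0)",
                  source, es), class = "woodcarbon_validation")
  }
  tibble::as_tibble(x)
}

#' Read and validate a long-format demand table
#'
#' @param path CSV with columns country, product, year, consumption.
#' @return A validated tibble.
#' @export
read_demand <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("country", "product", "year", "consumption")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing column(s) %s", path,
                  paste(miss, collapse = ", ")),
          class = "woodcarbon_validation")
  }
  bad <- which(!x$product %in% c("llp", "slp", "vslp_wfl", "vslp_ind"))
  if (length(bad) > 0) {
    abort(sprintf("%s: column `product`, row(s) %s: unknown product", path,
                  paste(head(bad, 5), collapse = ", ")),
          class = "woodcarbon_validation")
  }
  bad <- which(x$consumption < 0)
  if (length(bad) > 0) {
    abort(sprintf("%s: column `consumption`, row(s) %s: must be >= 0", path,
                  paste(head(bad, 5), collapse = ", ")),
          class = "woodcarbon_validation")
  }
  tibble::as_tibble(x)
}

#' Read a growth-band table
#'
#' Delimited text with columns country, forest_type
#' (plantation|secondary), young_rate, old_rate, root_shoot_coef,
#' root_shoot_exp.
#'
#' @param path CSV path.
#' @return A validated tibble.
#' @export
read_growth_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("country", "forest_type", "young_rate", "old_rate",
            "root_shoot_coef", "root_shoot_exp")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing column(s) %s", path,
                  paste(miss, collapse = ", ")),
          class = "woodcarbon_validation")
  }
  bad <- which(!x$forest_type %in% c("plantation", "secondary"))
  if (length(bad) > 0) {
    abort(sprintf("%s: column `forest_type`, row(s) %s: must be plantation or secondary",
                  path, paste(head(bad, 5), collapse = ", ")),
          class = "woodcarbon_validation")
  }
  bad <- which(!(x$young_rate > x$old_rate & x$old_rate > 0))
  if (length(bad) > 0) {
    abort(sprintf("%s: column `young_rate`, row(s) %s: need young > old > 0",
                  path, paste(head(bad, 5), collapse = ", ")),
          class = "woodcarbon_validation")
  }
  tibble::as_tibble(x)
}

#' Run configuration
#'
#' @param scenario Scenario id 1-7.
#' @param discount_rate Discount rate (default 0.04).
#' @param horizon Valuation horizon, 40 or 100 (default 40).
#' @param years Study years (default 2010:2050).
#' @param seed Integer seed for the synthetic world (default 1).
#' @param out_dir Output directory (default "results").
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenario = 1, discount_rate = 0.04, horizon = 40,
                       years = 2010:2050, seed = 1, out_dir = "results") {
  spec <- discount_spec(discount_rate, horizon)   # validates both
  if (!scenario %in% 1:7) abort("`scenario` must be 1..7.",
                                class = "woodcarbon_error")
  structure(list(scenario = as.integer(scenario), discount = spec,
                 years = years, seed = as.integer(seed),
                 out_dir = out_dir), class = "run_config")
}

#' Write scenario results and a reproducibility manifest
#'
#' Writes the scenario summary, the per-year harvest ledger and the
#' supply plan as tidy CSV plus a JSON manifest (configuration, seed,
#' package version). Files are written to a temporary name and renamed,
#' so a failed run never leaves truncated files.
#'
#' @param result A `scenario_result` from [run_scenario()].
#' @param config A [run_config()].
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, config) {
  stopifnot(inherits(result, "scenario_result"),
            inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  safe_write <- function(writer, obj, file) {
    tmp <- paste0(file, ".tmp")
    writer(obj, tmp)
    file.rename(tmp, file)
    file
  }
  paths <- c(
    safe_write(readr::write_csv, result$summary,
               file.path(config$out_dir, "summary.csv")),
    safe_write(readr::write_csv, result$ledger,
               file.path(config$out_dir, "ledger.csv")),
    safe_write(readr::write_csv, result$plan,
               file.path(config$out_dir, "plan.csv")),
    safe_write(function(x, f) jsonlite::write_json(x, f, auto_unbox = TRUE,
                                                   digits = NA),
               list(scenario = config$scenario,
                    discount_rate = config$discount$d,
                    horizon = config$discount$N,
                    years = range(config$years),
                    seed = config$seed,
                    package_version =
                      as.character(utils::packageVersion("woodcarbon"))),
               file.path(config$out_dir, "manifest.json"))
  )
  invisible(paths)
}
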