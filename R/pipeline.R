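# Configuration-driven orchestration: simulate (or load) inputs, run the
# enabled indicator stages in dependency order, and emit one consolidated
# indicator table plus a run manifest.

#' Pipeline run configuration
#'
#' @param mode "synthetic" (generate all inputs from the scenario) is the
#'   only input mode shipped; "files" is reserved.
#' @param seed master seed (mandatory in synthetic mode); forwarded to the
#'   climate and panel scenarios.
#' @param scenario,panel named lists of overrides for [climate_scenario()]
#'   and [panel_scenario()].
#' @param indicators character vector of stages to run; subset of
#'   `c("summer", "heatwave", "risk_hours", "labour", "mortality", "spei",
#'   "crops", "sst", "dengue", "malaria", "vibrio", "fies",
#'   "econ_mortality", "econ_earnings", "econ_carbon", "greenness",
#'   "elevation")`.
#' @param baseline heatwave/climatology baseline years.
#' @param reference_decade,comparison_decade year vectors for decadal
#'   comparisons.
#' @param target_year single year for year-specific stages.
#' @param heatwave list: percentile, min_duration_days, window_days.
#' @param risk_thresholds named WBGT cut-points c(moderate=, high=).
#' @param mortality list: beta_mort, death_rate_65plus (annual baseline
#'   deaths as a fraction of the 65+ population).
#' @param panel_years years covered by the country-year panel.
#' @param out optional output directory; when set, `indicators.csv` and
#'   `manifest.json` are written there.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(mode = "synthetic", seed = 42L,
                       scenario = list(), panel = list(),
                       indicators = NULL,
                       baseline = c(1986L, 2005L),
                       reference_decade = 1980:1989,
                       comparison_decade = 2020:2029,
                       target_year = 2029L,
                       heatwave = list(percentile = 0.95, min_duration_days = 2L,
                                       window_days = 1L),
                       risk_thresholds = c(moderate = 23, high = 28),
                       mortality = list(beta_mort = 0.05, death_rate_65plus = 0.05),
                       panel_years = 2010:2029,
                       out = NULL) {
  all_stages <- c("summer", "heatwave", "risk_hours", "labour", "mortality",
                  "spei", "crops", "sst", "dengue", "malaria", "vibrio",
                  "fies", "econ_mortality", "econ_earnings", "econ_carbon",
                  "greenness", "elevation")
  if (is.null(indicators)) indicators <- all_stages
  unknown <- setdiff(indicators, all_stages)
  if (length(unknown)) stop("unknown indicator stage(s): ",
                            paste(unknown, collapse = ", "))
  if (mode != "synthetic") stop("only synthetic input mode is implemented")
  if (is.null(seed)) stop("seed is mandatory in synthetic mode")
  deps <- list(fies = "heatwave", econ_mortality = "mortality",
               econ_earnings = "labour")
  for (st in names(deps)) {
    if (st %in% indicators && !all(deps[[st]] %in% indicators))
      stop(sprintf("stage '%s' requires stage '%s' to be enabled",
                   st, paste(deps[[st]], collapse = ", ")))
  }
  cfg <- list(mode = mode, seed = as.integer(seed), scenario = scenario,
              panel = panel, indicators = indicators, baseline = as.integer(baseline),
              reference_decade = reference_decade,
              comparison_decade = comparison_decade,
              target_year = as.integer(target_year), heatwave = heatwave,
              risk_thresholds = risk_thresholds, mortality = mortality,
              panel_years = panel_years, out = out)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  expand <- function(x) if (is.list(x) && !is.null(x$from) && !is.null(x$to))
    seq(x$from, x$to) else x
  for (k in c("reference_decade", "comparison_decade", "panel_years"))
    if (!is.null(y[[k]])) y[[k]] <- expand(y[[k]])
  do.call(run_config, y)
}

stage_log <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  dt <- proc.time()[["elapsed"]] - t0
  message(sprintf("INFO [%s] completed in %.2f s", name, dt))
  attr(res, "elapsed") <- dt
  res
}

#' Run the full indicator suite
#'
#' Generates (or, in future modes, loads) the inputs, runs the enabled
#' stages in dependency order (climatologies, then heatwaves, then
#' everything downstream), and returns one consolidated [indicator_table()]
#' plus a manifest recording the package version, seeds, per-stage row
#' counts and wall times. Identical configuration and seed give an
#' identical indicator table; when `config$out` is set, `indicators.csv`
#' and `manifest.json` are written there (partial outputs are removed on
#' failure).
#'
#' @param config a [run_config()].
#' @return list with `table` (the consolidated `indicator_table`) and
#'   `manifest`.
#' @export
run_suite <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  enabled <- config$indicators
  sc <- do.call(climate_scenario, c(config$scenario, list(seed = config$seed)))
  fields <- stage_log("simulate_climate", gen_climate_fields(sc))
  pr <- stage_log("simulate_population", gen_population_and_regions(sc))
  pop <- pr$pop; regions <- pr$regions
  baseline <- config$baseline
  base_years <- seq(baseline[1L], baseline[2L])
  ref <- config$reference_decade; cmp <- config$comparison_decade
  tgt <- config$target_year
  results <- list()
  timings <- list()
  keep <- function(name, tab) {
    timings[[name]] <<- attr(tab, "elapsed")
    results[[name]] <<- tab
  }

  need_hw <- any(c("heatwave", "fies") %in% enabled)
  hw <- NULL
  if (need_hw) {
    hp <- heatwave_params(percentile = config$heatwave$percentile,
                          baseline = baseline,
                          min_duration_days = config$heatwave$min_duration_days)
    wd <- config$heatwave$window_days
    clim_min <- stage_log("climatology_tmin", build_percentile_climatology(
      fields$tmin, baseline, hp$percentile, wd))
    clim_max <- stage_log("climatology_tmax", build_percentile_climatology(
      fields$tmax, baseline, hp$percentile, wd))
    hw <- stage_log("detect_heatwaves",
                    detect_heatwaves(fields$tmin, fields$tmax, clim_min, clim_max, hp))
  }

  if ("summer" %in% enabled)
    keep("summer", stage_log("summer", summer_exposure_anomaly(
      fields$tmean, pop, regions, base_years, tgt)))

  if ("heatwave" %in% enabled) {
    keep("heatwave_under1", stage_log("heatwave_under1", heatwave_exposure(
      hw, pop, "under1", base_years, cmp, regions)))
    keep("heatwave_65plus", stage_log("heatwave_65plus", heatwave_exposure(
      hw, pop, "65plus", base_years, cmp, regions)))
  }

  if ("risk_hours" %in% enabled)
    keep("risk_hours", stage_log("risk_hours", wbgt_risk_hours(
      fields$tmin, fields$tmax, fields$rh, pop, regions,
      thresholds = config$risk_thresholds, baseline = base_years, target = cmp)))

  labour <- NULL
  if ("labour" %in% enabled) {
    workers <- gen_working_population(pop, regions)
    labour <- stage_log("labour", labour_hours_lost(
      fields$tmin, fields$tmax, fields$rh, workers, hothaps_params(),
      regions, target = cmp))
    keep("labour", labour$table)
    timings[["labour"]] <- attr(labour, "elapsed")
  }

  mort <- NULL
  if ("mortality" %in% enabled) {
    clim_mean <- stage_log("climatology_tmean", build_percentile_climatology(
      fields$tmean, baseline, config$heatwave$percentile,
      config$heatwave$window_days))
    pop65 <- population_vector(pop, "65plus")
    deaths <- tapply(pop65, regions$country_code, sum) *
      config$mortality$death_rate_65plus
    mp <- mortality_er_params(config$heatwave$percentile,
                              config$mortality$beta_mort,
                              baseline_deaths = deaths)
    mort <- stage_log("mortality", heat_attributable_mortality(
      fields$tmean, clim_mean, pop, regions, mp, period1 = ref, period2 = cmp))
    keep("mortality", mort$table)
    timings[["mortality"]] <- attr(mort, "elapsed")
  }

  need_monthly <- any(c("spei", "dengue", "malaria") %in% enabled)
  if (need_monthly) {
    tm_mon <- monthly_climate(fields$tmean, "mean")
    pr_mon <- monthly_climate(fields$precip, "sum")
  }

  if ("spei" %in% enabled) {
    sp <- spei_params(reference_decade = ref, comparison_decade = cmp)
    pet <- stage_log("pet", thornthwaite_pet(tm_mon))
    spx <- stage_log("spei", spei(pr_mon, pet, sp))
    keep("spei", stage_log("drought_area", extreme_drought_area(spx, regions, sp)))
  }

  if ("crops" %in% enabled) {
    cpar <- crop_params()
    for (crop in c("maize", "winter_wheat")) {
      cs <- stage_log(paste0("crop_", crop), crop_season_length(
        fields$tmean, cpar, crop, regions, reference = ref, comparison = cmp))
      keep(paste0("crop_", crop), cs$table)
    }
  }

  if ("sst" %in% enabled)
    keep("sst", stage_log("sst", coastal_sst_anomaly(fields$sst, regions, ref, cmp)))

  if ("dengue" %in% enabled)
    keep("dengue", stage_log("dengue", dengue_r0_suitability(
      tm_mon, pr_mon, pop, dengue_params(), ref, cmp)))

  if ("malaria" %in% enabled) {
    rh_mon <- monthly_climate(fields$rh, "mean")
    keep("malaria", stage_log("malaria", malaria_suitable_months(
      tm_mon, pr_mon, rh_mon, regions, malaria_thresholds(), ref, cmp)))
  }

  if ("vibrio" %in% enabled)
    keep("vibrio", stage_log("vibrio", vibrio_coastal_suitability(
      fields$sst, fields$sss, regions, vibrio_thresholds(), ref, cmp)))

  panel <- NULL
  if (any(c("fies", "econ_mortality", "econ_earnings", "econ_carbon") %in% enabled)) {
    n_co <- length(unique(stats::na.omit(regions$country_code)))
    ps <- do.call(panel_scenario, c(config$panel, list(
      n_countries = n_co, years = config$panel_years, seed = config$seed)))
    if (need_hw) {
      expo_all <- growing_season_heatwave_days(hw, regions, baseline = base_years)
      expo <- expo_all[expo_all$year %in% config$panel_years, ]
    } else {
      expo <- expand.grid(country = sort(unique(stats::na.omit(regions$country_code))),
                          year = config$panel_years, stringsAsFactors = FALSE)
      expo$hw_anomaly <- 0
    }
    panel <- stage_log("panel", gen_panel_tables(ps, expo))
  }

  if ("fies" %in% enabled) {
    fit <- stage_log("fies_fit", fit_fies_regression(panel, expo, regression_spec()))
    keep("fies", stage_log("fies_attribution", attribute_food_insecurity(
      fit, expo, panel, tgt)))
    results[["fies_beta"]] <- indicator_table(
      "fies_beta_hat", "GLOBAL", period_label(config$panel_years),
      unname(fit$beta_hat[1L]), "pp/heatwave-day")
  }

  hdi_map <- unique(regions[!is.na(regions$country_code),
                            c("country_code", "hdi_group")])
  econ <- if (!is.null(panel)) {
    e <- econ_rows(panel, tgt)
    e$hdi_group <- hdi_map$hdi_group[match(e$country, hdi_map$country_code)]
    e
  }

  if ("econ_mortality" %in% enabled)
    keep("econ_mortality", stage_log("econ_mortality", monetise_heat_mortality(
      mort$yll_by_country, econ, period = period_label(cmp))))

  if ("econ_earnings" %in% enabled)
    keep("econ_earnings", stage_log("econ_earnings", lost_earnings(
      labour$by_country_sector, econ, tgt)))

  if ("econ_carbon" %in% enabled)
    keep("econ_carbon", stage_log("econ_carbon", net_carbon_price(econ, tgt)))

  if ("greenness" %in% enabled)
    keep("greenness", stage_log("greenness", urban_greenness(regions, pop)))

  if ("elevation" %in% enabled)
    keep("elevation", stage_log("elevation", population_below_elevation(
      regions, pop, threshold_m = 1)))

  table <- do.call(bind_indicators, unname(results))
  manifest <- list(
    package = "climind",
    version = as.character(utils::packageVersion("climind")),
    seed = config$seed,
    stages = names(results),
    rows = nrow(table),
    config_hash = sum(utf8ToInt(paste(deparse(config[setdiff(names(config), "out")]),
                                      collapse = ""))),
    timings_s = lapply(timings, function(x) if (is.null(x)) NA_real_ else round(x, 3))
  )
  if (!is.null(config$out)) {
    dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
    csv <- file.path(config$out, "indicators.csv")
    ok <- FALSE
    on.exit(if (!ok && file.exists(csv)) unlink(csv), add = TRUE)
    write_indicator_table(table, csv)
    jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    ok <- TRUE
  }
  list(table = table, manifest = manifest)
}
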