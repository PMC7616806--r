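# Seeded synthetic inputs with known statistical structure: every indicator
# stage can be exercised, and calibrations checked, without any download.
#
# Daily climate = latitude-dependent mean state
#                 + hemisphere-phased seasonal cycle
#                 + linear secular warming trend
#                 + stationary AR(1) daily noise.
# Population is allocated log-normally over land cells and rescaled to exact
# age-group totals; countries are contiguous blocks of land cells.

#' Synthetic climate scenario
#'
#' Bundles every knob of the synthetic climate generator. The defaults are
#' the package's desk-scale study conditions: a 12 x 24 global grid, 50
#' years (1980-2029, 365-day no-leap calendar), a 0.3 degC/decade warming
#' trend, and AR(1) daily noise (coefficient 0.7) so that warm spells have
#' realistic multi-day persistence.
#'
#' @param n_lat,n_lon grid size (cell centres are evenly spaced).
#' @param lat_range,lon_range grid extent in degrees.
#' @param years integer vector of consecutive years.
#' @param mean_climate optional per-cell annual-mean temperature array
#'   (n_lat x n_lon, degC); default is a smooth pole-to-equator profile.
#' @param seasonal_amplitude peak seasonal half-range in degC at the highest
#'   latitude; scaled down towards the equator.
#' @param warming_trend linear trend in degC per decade.
#' @param daily_noise_sd stationary standard deviation of daily noise, degC.
#' @param ar1_coeff lag-1 autocorrelation of the daily noise, in [0, 1).
#' @param diurnal_range Tmax - Tmin, degC.
#' @param precip_mean_mm mean monthly precipitation (scalar or length 12), mm.
#' @param precip_shape gamma shape of daily precipitation draws.
#' @param rh_mean_pct,rh_noise_sd mean and daily noise sd of relative humidity, %.
#' @param sst_offset additive offset on the sea-surface temperature profile, degC.
#' @param sss_mean mean sea-surface salinity, practical salinity units.
#' @param sss_spatial_sd across-cell sd of the static salinity pattern, psu.
#' @param seed master integer seed; per-variable child seeds are derived by
#'   fixed offsets (+101 temperature, +202 precipitation, +303 humidity,
#'   +404 SST, +505 salinity, +606 population/regions, +707 panel).
#' @return object of class `climate_scenario`.
#' @export
climate_scenario <- function(n_lat = 12L, n_lon = 24L,
                             lat_range = c(-66, 66), lon_range = c(-180, 180),
                             years = 1980:2029,
                             mean_climate = NULL,
                             seasonal_amplitude = 10,
                             warming_trend = 0.3,
                             daily_noise_sd = 2,
                             ar1_coeff = 0.7,
                             diurnal_range = 8,
                             precip_mean_mm = 80,
                             precip_shape = 2,
                             rh_mean_pct = 65,
                             rh_noise_sd = 8,
                             sst_offset = 0,
                             sss_mean = 30,
                             sss_spatial_sd = 4,
                             seed = 42L) {
  if (ar1_coeff < 0 || ar1_coeff >= 1) stop("ar1_coeff must lie in [0, 1)")
  if (daily_noise_sd < 0) stop("daily_noise_sd must be >= 0")
  if (diurnal_range < 0) stop("diurnal_range must be >= 0")
  if (any(precip_mean_mm < 0) || precip_shape <= 0) stop("invalid precipitation parameters")
  if (length(precip_mean_mm) == 1L) precip_mean_mm <- rep(precip_mean_mm, 12L)
  if (length(precip_mean_mm) != 12L) stop("precip_mean_mm must be scalar or length 12")
  if (any(diff(years) != 1L)) stop("years must be consecutive")
  structure(as.list(environment()), class = "climate_scenario")
}

scenario_lats <- function(sc) {
  d <- (sc$lat_range[2] - sc$lat_range[1]) / sc$n_lat
  sc$lat_range[1] + (seq_len(sc$n_lat) - 0.5) * d
}

scenario_lons <- function(sc) {
  d <- (sc$lon_range[2] - sc$lon_range[1]) / sc$n_lon
  sc$lon_range[1] + (seq_len(sc$n_lon) - 0.5) * d
}

# AR(1) series per column with stationary sd `sd_stat`
ar1_noise <- function(ntime, ncell, phi, sd_stat) {
  if (sd_stat == 0) return(matrix(0, ntime, ncell))
  innov_sd <- sd_stat * sqrt(1 - phi^2)
  z <- matrix(stats::rnorm(ntime * ncell, sd = innov_sd), ntime, ncell)
  z[1L, ] <- stats::rnorm(ncell, sd = sd_stat)  # start at stationarity
  if (phi == 0) return(z)
  apply(z, 2L, function(x) as.numeric(stats::filter(x, phi, method = "recursive")))
}

#' Generate the full set of synthetic daily climate fields
#'
#' Daily mean temperature follows
#' `mean_climate + A(lat) * cos(2*pi*(doy - peak_doy)/365) + trend*(year - year0)/10 + AR(1) noise`
#' with the seasonal peak on day 196 in the northern hemisphere and day 15
#' in the southern; Tmax/Tmin are Tmean +/- diurnal_range/2; precipitation
#' is i.i.d. gamma with month-specific mean; identical seeds give identical
#' output.
#'
#' @param sc a [climate_scenario()].
#' @return named list of [climate_field()]s: tmean, tmin, tmax, precip, rh,
#'   sst, sss.
#' @export
gen_climate_fields <- function(sc) {
  lats <- scenario_lats(sc); lons <- scenario_lons(sc)
  nlat <- length(lats); nlon <- length(lons); ncell <- nlat * nlon
  nyears <- length(sc$years)
  ntime <- nyears * DAYS_PER_YEAR
  years <- rep(sc$years, each = DAYS_PER_YEAR)
  doys <- rep(seq_len(DAYS_PER_YEAR), times = nyears)

  ct <- cell_table(lats, lons)
  abslat <- abs(ct$lat)
  maxlat <- max(abslat)
  base <- if (is.null(sc$mean_climate)) {
    27 - 22 * (abslat / max(maxlat, 1))^2
  } else {
    as.vector(sc$mean_climate)
  }
  amp <- sc$seasonal_amplitude * (0.2 + 0.8 * abslat / max(maxlat, 1))
  peak <- ifelse(ct$lat >= 0, 196, 15)

  seasonal <- outer(doys, seq_len(ncell),
                    function(d, k) amp[k] * cos(2 * pi * (d - peak[k]) / DAYS_PER_YEAR))
  trend <- sc$warming_trend * (years - sc$years[1L]) / 10

  set.seed(sc$seed + 101L)
  noise <- ar1_noise(ntime, ncell, sc$ar1_coeff, sc$daily_noise_sd)
  tmean_m <- sweep(seasonal + noise, 2L, base, "+") + trend

  as_field <- function(var, units, m) {
    arr <- m
    dim(arr) <- c(ntime, nlat, nlon)
    climate_field(var, units, years, doys, lats, lons, arr, calendar = "noleap")
  }

  tmean <- as_field("tmean", "degC", tmean_m)
  tmax <- as_field("tmax", "degC", tmean_m + sc$diurnal_range / 2)
  tmin <- as_field("tmin", "degC", tmean_m - sc$diurnal_range / 2)

  set.seed(sc$seed + 202L)
  mo <- doy_to_month(doys)
  daily_mean <- sc$precip_mean_mm[mo] / NOLEAP_MONTH_LENGTHS[mo]
  pr_m <- matrix(stats::rgamma(ntime * ncell, shape = sc$precip_shape,
                               scale = rep(daily_mean, times = ncell) / sc$precip_shape),
                 ntime, ncell)
  precip <- as_field("precip", "mm", pr_m)

  set.seed(sc$seed + 303L)
  rh_m <- matrix(sc$rh_mean_pct + stats::rnorm(ntime * ncell, sd = sc$rh_noise_sd),
                 ntime, ncell)
  rh_m <- pmin(pmax(rh_m, 5), 100)
  rh <- as_field("rh", "%", rh_m)

  set.seed(sc$seed + 404L)
  sst_base <- 26 - 30 * (abslat / 90)^2 + sc$sst_offset
  sst_seasonal <- outer(doys, seq_len(ncell),
                        function(d, k) 0.3 * amp[k] * cos(2 * pi * (d - peak[k]) / DAYS_PER_YEAR))
  sst_m <- sweep(sst_seasonal, 2L, sst_base, "+") + trend +
    matrix(stats::rnorm(ntime * ncell, sd = 0.5), ntime, ncell)
  sst <- as_field("sst", "degC", sst_m)

  set.seed(sc$seed + 505L)
  sss_pattern <- sc$sss_mean + stats::rnorm(ncell, sd = sc$sss_spatial_sd)
  sss_m <- sweep(matrix(stats::rnorm(ntime * ncell, sd = 0.5), ntime, ncell),
                 2L, sss_pattern, "+")
  sss <- as_field("sss", "psu", sss_m)

  list(tmean = tmean, tmin = tmin, tmax = tmax, precip = precip,
       rh = rh, sst = sst, sss = sss)
}

#' Generate a synthetic population grid and region table
#'
#' Land is laid out as two rectangular continents; countries are contiguous
#' blocks of land cells cycling through the four HDI groups; population is
#' allocated log-normally across land cells and rescaled to exact age-group
#' totals; coastal cells (land with a 4-neighbour ocean cell) include a
#' low-lying elevation band, a share of interior cells is highland
#' (>= 1500 m), and the most populous land cells become urban centres.
#'
#' @param sc a [climate_scenario()] (supplies the grid and master seed).
#' @param age_totals named non-negative totals per age group.
#' @param n_countries number of countries (at most the number of land cells).
#' @param urban_fraction fraction of land cells promoted to urban centres.
#' @return list with elements `pop` ([population_grid()]) and `regions`
#'   ([region_table()]).
#' @export
gen_population_and_regions <- function(sc,
                                       age_totals = c(under1 = 1e7, "1to64" = 6e8,
                                                      "65plus" = 6e7),
                                       n_countries = 6L,
                                       urban_fraction = 0.1) {
  if (any(age_totals < 0)) stop("age-group totals must be non-negative")
  lats <- scenario_lats(sc); lons <- scenario_lons(sc)
  nlat <- length(lats); nlon <- length(lons)
  ct <- cell_table(lats, lons)
  set.seed(sc$seed + 606L)

  # two rectangular continents, keeping the outermost latitude rows as ocean
  lon_block <- function(i0, i1) ct$lon_idx >= i0 & ct$lon_idx <= i1
  interior <- ct$lat_idx > 1L & ct$lat_idx < nlat
  b1 <- max(2L, round(nlon * 0.15)); b2 <- min(nlon - 1L, round(nlon * 0.42))
  b3 <- max(2L, round(nlon * 0.55)); b4 <- min(nlon - 1L, round(nlon * 0.85))
  is_land <- interior & (lon_block(b1, b2) | lon_block(b3, b4))
  land_idx <- which(is_land)
  if (n_countries > length(land_idx)) stop("more countries than land cells")

  # 4-neighbour coastal flag
  landm <- matrix(FALSE, nlat, nlon)
  landm[cbind(ct$lat_idx[is_land], ct$lon_idx[is_land])] <- TRUE
  nb_ocean <- function(i, j) {
    # out-of-grid neighbours count as ocean
    up <- if (i > 1L) landm[i - 1L, j] else FALSE
    down <- if (i < nlat) landm[i + 1L, j] else FALSE
    left <- if (j > 1L) landm[i, j - 1L] else FALSE
    right <- if (j < nlon) landm[i, j + 1L] else FALSE
    !(up && down && left && right)
  }
  is_coastal <- rep(FALSE, nrow(ct))
  is_coastal[land_idx] <- vapply(land_idx, function(k)
    nb_ocean(ct$lat_idx[k], ct$lon_idx[k]), logical(1))

  # contiguous countries: order land cells by (lon, lat), split into chunks
  ord <- land_idx[order(ct$lon_idx[land_idx], ct$lat_idx[land_idx])]
  chunk <- cut(seq_along(ord), breaks = n_countries, labels = FALSE)
  country <- rep(NA_character_, nrow(ct))
  country[ord] <- paste0("SY", LETTERS[chunk])
  hdi_levels <- c("low", "medium", "high", "very_high")
  country_hdi <- stats::setNames(hdi_levels[((seq_len(n_countries) - 1L) %% 4L) + 1L],
                                 paste0("SY", LETTERS[seq_len(n_countries)]))
  hdi <- rep(NA_character_, nrow(ct))
  hdi[land_idx] <- country_hdi[country[land_idx]]

  # elevation: lognormal interior, low-lying coastal band, highland share
  elevation <- rep(NA_real_, nrow(ct))
  elevation[land_idx] <- stats::rlnorm(length(land_idx), meanlog = log(200), sdlog = 1)
  coast_cells <- which(is_coastal)
  low_band <- coast_cells[stats::runif(length(coast_cells)) < 0.6]
  elevation[low_band] <- stats::runif(length(low_band), 0, 3)
  inland <- setdiff(land_idx, coast_cells)
  high_cells <- inland[stats::runif(length(inland)) < 0.12]
  elevation[high_cells] <- stats::runif(length(high_cells), 1500, 3000)

  land_class <- rep(NA_character_, nrow(ct))
  land_class[land_idx] <- sample(c("cropland", "forest", "grassland", "shrubland"),
                                 length(land_idx), replace = TRUE,
                                 prob = c(0.35, 0.3, 0.25, 0.1))

  # log-normal population weights shared across groups, exact totals per group
  w <- stats::rlnorm(length(land_idx), meanlog = 0, sdlog = 1.2)
  groups <- names(age_totals)
  counts <- array(0, dim = c(length(groups), nlat, nlon))
  for (g in seq_along(groups)) {
    v <- rep(0, nrow(ct))
    v[land_idx] <- age_totals[[g]] * w / sum(w)
    v[land_idx[length(land_idx)]] <- v[land_idx[length(land_idx)]] +
      (age_totals[[g]] - sum(v))  # exact conservation
    counts[g, , ] <- matrix(v, nlat, nlon)
  }
  pop <- population_grid(lats, lons, groups, counts)

  total_pop <- colSums(matrix(counts, nrow = length(groups)))
  n_urban <- max(0L, round(urban_fraction * length(land_idx)))
  urban_id <- rep(NA_integer_, nrow(ct))
  if (n_urban > 0L) {
    urb <- land_idx[order(total_pop[land_idx], decreasing = TRUE)][seq_len(n_urban)]
    urban_id[urb] <- seq_len(n_urban)
  }

  ndvi <- rep(NA_real_, nrow(ct))
  ndvi[land_idx] <- stats::runif(length(land_idx), 0.05, 0.85)
  if (n_urban > 0L) ndvi[!is.na(urban_id)] <- stats::runif(n_urban, 0, 0.8)

  regions <- region_table(data.frame(
    ct,
    country_code = country, hdi_group = hdi, elevation_m = elevation,
    is_land = is_land, is_coastal = is_coastal, land_class = land_class,
    urban_centre_id = urban_id, ndvi = ndvi, stringsAsFactors = FALSE
  ))
  list(pop = pop, regions = regions)
}

#' Derive a sector-stratified working population grid
#'
#' Splits the working-age group into the four labour sectors, with the
#' agricultural share set per HDI group (highest in low-HDI countries, as in
#' observed employment structure) and the remainder divided between
#' construction, manufacturing and services.
#'
#' @param pop a [population_grid()] containing the `working_group`.
#' @param regions matching [region_table()].
#' @param working_group age-group label to split (default "1to64").
#' @param participation labour-force participation rate applied to the group.
#' @param ag_share named agricultural share per HDI group.
#' @return a [population_grid()] with groups agriculture, construction,
#'   manufacturing, services.
#' @export
gen_working_population <- function(pop, regions, working_group = "1to64",
                                   participation = 0.6,
                                   ag_share = c(low = 0.6, medium = 0.4,
                                                high = 0.2, very_high = 0.08)) {
  base <- population_vector(pop, working_group) * participation
  ag <- ifelse(is.na(regions$hdi_group), 0, ag_share[regions$hdi_group]) * base
  rest <- base - ag
  nlat <- length(pop$lats); nlon <- length(pop$lons)
  counts <- array(0, dim = c(4L, nlat, nlon))
  counts[1L, , ] <- matrix(ag, nlat, nlon)
  counts[2L, , ] <- matrix(rest * 0.15, nlat, nlon)
  counts[3L, , ] <- matrix(rest * 0.30, nlat, nlon)
  counts[4L, , ] <- matrix(rest * 0.55, nlat, nlon)
  population_grid(pop$lats, pop$lons,
                  c("agriculture", "construction", "manufacturing", "services"),
                  counts)
}

#' Synthetic country-year panel scenario
#'
#' Parameters of the panel generator used by the food-insecurity regression
#' and the economics stages. Food-insecurity prevalence is generated with a
#' known linear effect of growing-season heatwave-day anomalies:
#' `prev = clip(base + alpha_c + gamma_t + beta_fies * anomaly / 100 + eps, 0, 1)`.
#'
#' @param n_countries,years panel dimensions.
#' @param beta_fies effect size, percentage points of prevalence per
#'   heatwave-day anomaly.
#' @param baseline_prev baseline prevalence (proportion).
#' @param country_effects_sd,year_effects_sd,noise_sd standard deviations of
#'   country effects, year effects and observation noise (proportions).
#' @param vsly_multiple VSLY as a multiple of average annual income.
#' @param residual_life_expectancy years of life lost per death in the 65+
#'   group.
#' @param seed integer seed.
#' @return object of class `panel_scenario`.
#' @export
panel_scenario <- function(n_countries = 6L, years = 2010:2029,
                           beta_fies = 0.5, baseline_prev = 0.2,
                           country_effects_sd = 0.05, year_effects_sd = 0.01,
                           noise_sd = 0.02,
                           vsly_multiple = 2.5, residual_life_expectancy = 12,
                           seed = 42L) {
  if (n_countries < 2L || length(years) < 2L) stop("panel needs >= 2 countries and >= 2 years")
  structure(as.list(environment()), class = "panel_scenario")
}

#' Generate a synthetic country-year panel table
#'
#' @param ps a [panel_scenario()].
#' @param hw_anomalies data.frame with columns country, year, hw_anomaly
#'   (growing-season heatwave-day anomaly) covering every (country, year).
#' @return data.frame of class `panel_table` with prevalence, population and
#'   the per-country economic columns.
#' @export
gen_panel_tables <- function(ps, hw_anomalies) {
  countries <- sort(unique(hw_anomalies$country))
  years <- sort(unique(hw_anomalies$year))
  if (length(countries) != ps$n_countries)
    stop("hw_anomalies countries do not match the scenario")
  full <- expand.grid(country = countries, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- merge(full, hw_anomalies, by = c("country", "year"), all.x = TRUE)
  if (anyNA(m$hw_anomaly)) stop("hw_anomalies must cover every (country, year)")

  set.seed(ps$seed + 707L)
  alpha <- stats::setNames(stats::rnorm(length(countries), sd = ps$country_effects_sd),
                           countries)
  gamma <- stats::setNames(stats::rnorm(length(years), sd = ps$year_effects_sd),
                           as.character(years))
  eps <- stats::rnorm(nrow(m), sd = ps$noise_sd)
  prev <- ps$baseline_prev + alpha[m$country] + gamma[as.character(m$year)] +
    ps$beta_fies * m$hw_anomaly / 100 + eps
  m$prevalence <- pmin(pmax(prev, 0), 1)

  population <- stats::setNames(stats::rlnorm(length(countries),
                                              meanlog = log(5e7), sdlog = 0.8),
                                countries)
  income <- stats::setNames(stats::rlnorm(length(countries),
                                          meanlog = log(1.2e4), sdlog = 1),
                            countries)
  gdp <- population * income
  wage_base <- income / 2000  # hourly wage from annual income, 2000 h/yr
  econ <- data.frame(
    country = countries,
    population = population,
    gdp = gdp,
    average_income = income,
    vsly = ps$vsly_multiple * income,
    residual_life_expectancy = ps$residual_life_expectancy,
    wage_agriculture = wage_base * 0.6,
    wage_construction = wage_base * 0.9,
    wage_manufacturing = wage_base * 1.0,
    wage_services = wage_base * 1.1,
    carbon_revenue = 0.002 * gdp * stats::rgamma(length(countries), 2, 2),
    fossil_subsidies = 0.008 * gdp * stats::rgamma(length(countries), 2, 2),
    co2_emissions = population * 5 * stats::rlnorm(length(countries), 0, 0.3),
    health_expenditure = 0.07 * gdp,
    stringsAsFactors = FALSE
  )
  out <- merge(m, econ, by = "country")
  out <- out[order(out$country, out$year), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("panel_table", "data.frame")
  out
}
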