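# Heat hazard and exposure indicators: summer exposure anomaly, heatwave
# person-days, WBGT heat-stress risk hours, sectoral labour capacity loss,
# and heat-attributable mortality.

#' Heatwave definition parameters
#'
#' A heatwave is a period of `min_duration_days` or more consecutive days in
#' which both the daily minimum and maximum temperatures are strictly above
#' their baseline percentile thresholds.
#'
#' @param percentile threshold percentile (default 0.95).
#' @param baseline baseline years for the climatology (default 1986-2005).
#' @param min_duration_days minimum run length in days (default 2).
#' @param require_both_min_and_max if FALSE, only Tmax is tested.
#' @return object of class `heatwave_params`.
#' @export
heatwave_params <- function(percentile = 0.95, baseline = c(1986L, 2005L),
                            min_duration_days = 2L,
                            require_both_min_and_max = TRUE) {
  if (min_duration_days < 1L) stop("min_duration_days must be >= 1")
  if (percentile <= 0 || percentile >= 1) stop("percentile must lie in (0, 1)")
  structure(list(percentile = percentile, baseline = as.integer(baseline),
                 min_duration_days = as.integer(min_duration_days),
                 require_both_min_and_max = require_both_min_and_max),
            class = "heatwave_params")
}

#' Keep only runs of TRUE of at least a minimum length
#'
#' Run-length filter shared by heatwave detection and coastal Vibrio
#' suitability: a position is kept iff it lies inside a maximal run of TRUE
#' of length >= `min_len`.
#'
#' @param x logical vector (NA treated as FALSE).
#' @param min_len minimum run length.
#' @return logical vector of the same length.
#' @export
flag_min_runs <- function(x, min_len) {
  x <- !is.na(x) & x
  if (!length(x)) return(logical(0))
  r <- rle(x)
  r$values <- r$values & r$lengths >= min_len
  inverse.rle(r)
}

#' Detect heatwave days
#'
#' A day is a candidate when Tmin and Tmax both exceed (strictly) their
#' per-cell, per-calendar-day percentile thresholds; a heatwave day is any
#' day inside a maximal run of at least `min_duration_days` consecutive
#' candidates. Runs are evaluated per cell over the continuous time axis,
#' so they may span year boundaries.
#'
#' @param tmin,tmax daily [climate_field()]s on the same grid and time axis.
#' @param clim_min,clim_max [build_percentile_climatology()] results for
#'   Tmin and Tmax, built from `params$baseline` at `params$percentile`.
#' @param params a [heatwave_params()].
#' @return a [climate_field()] named "heatwave_day" with 0/1 values.
#' @export
detect_heatwaves <- function(tmin, tmax, clim_min, clim_max,
                             params = heatwave_params()) {
  stop_if_grid_mismatch(tmin, tmax)
  for (cl in list(clim_min, clim_max)) {
    if (!identical(as.integer(cl$baseline), params$baseline) ||
        !isTRUE(all.equal(cl$percentile, params$percentile)))
      stop("climatology baseline/percentile do not match the heatwave parameters")
  }
  cand <- field_matrix(tmax) > threshold_matrix(clim_max, tmax)
  if (params$require_both_min_and_max)
    cand <- cand & (field_matrix(tmin) > threshold_matrix(clim_min, tmin))
  hw <- apply(cand, 2L, flag_min_runs, min_len = params$min_duration_days)
  arr <- array(as.numeric(hw),
               dim = c(length(tmin$years), length(tmin$lats), length(tmin$lons)))
  climate_field("heatwave_day", "dimensionless", tmin$years, tmin$doys,
                tmin$lats, tmin$lons, arr, calendar = tmin$calendar,
                dates = tmin$dates)
}

# per-(year, cell) mean over the hemisphere-appropriate summer days
# (JJA at and north of the equator; calendar-year DJF south of it)
summer_year_means <- function(field) {
  m <- field_matrix(field)
  ct <- cell_table(field$lats, field$lons)
  nh <- ct$lat >= 0
  jja <- field$doys >= 152L & field$doys <= 243L
  djf <- field$doys >= 335L | field$doys <= 59L
  yrs <- sort(unique(field$years))
  out <- matrix(NA_real_, length(yrs), nrow(ct))
  nh_m <- rowsum(m[jja, , drop = FALSE], field$years[jja]) /
    as.vector(table(field$years[jja]))
  sh_m <- rowsum(m[djf, , drop = FALSE], field$years[djf]) /
    as.vector(table(field$years[djf]))
  out[match(rownames(nh_m), as.character(yrs)), nh] <- nh_m[, nh]
  out[match(rownames(sh_m), as.character(yrs)), !nh] <- sh_m[, !nh]
  rownames(out) <- as.character(yrs)
  out
}

period_label <- function(years) {
  if (length(years) == 1L) as.character(years) else
    sprintf("%d-%d", min(years), max(years))
}

# weighted means over GLOBAL plus HDI groups; returns named vector
global_and_hdi_means <- function(x, weights, regions) {
  out <- c(GLOBAL = unname(weighted_regional_mean(x, weights, rep("GLOBAL", length(x)))))
  if (!is.null(regions)) {
    g <- weighted_regional_mean(x, weights, regions$hdi_group)
    out <- c(out, g)
  }
  out
}

#' Population- and area-weighted summer temperature exposure anomaly
#'
#' The mean summer (JJA north of the equator, DJF south of it) temperature
#' anomaly of the target period relative to the baseline, aggregated with
#' all-age population weights (the temperature people were exposed to) and
#' with cosine-latitude area weights (the plain climate signal), globally
#' and per HDI group.
#'
#' @param tmean daily mean-temperature [climate_field()].
#' @param pop a [population_grid()] on the same grid.
#' @param regions optional [region_table()] for HDI-group aggregation.
#' @param baseline,target year vectors.
#' @return an [indicator_table()] with rows
#'   `summer_exposure_anomaly_popweighted` and `_areaweighted`, units degC.
#' @export
summer_exposure_anomaly <- function(tmean, pop, regions = NULL,
                                    baseline = 1986:2005, target = 2021L) {
  stopifnot(all(baseline %in% tmean$years), all(target %in% tmean$years))
  if (!isTRUE(all.equal(pop$lats, tmean$lats)) ||
      !isTRUE(all.equal(pop$lons, tmean$lons))) stop("grid mismatch")
  sm <- summer_year_means(tmean)
  yrs <- as.integer(rownames(sm))
  anom <- colMeans(sm[yrs %in% target, , drop = FALSE]) -
    colMeans(sm[yrs %in% baseline, , drop = FALSE])
  pw <- colSums(matrix(pop$counts, nrow = length(pop$age_groups)))
  aw <- area_weights(tmean$lats, tmean$lons)
  vp <- global_and_hdi_means(anom, pw, regions)
  va <- global_and_hdi_means(anom, aw, regions)
  per <- period_label(target)
  bind_indicators(
    indicator_table("summer_exposure_anomaly_popweighted", names(vp), per, vp, "degC"),
    indicator_table("summer_exposure_anomaly_areaweighted", names(va), per, va, "degC")
  )
}

# annual heatwave-day counts per cell: [n_year, n_cell] matrix
annual_counts <- function(hw_field) {
  rowsum(field_matrix(hw_field), hw_field$years)
}

#' Heatwave exposure in person-days
#'
#' Person-days of heatwave for one age group: the sum over cells of the
#' group's population times the cell's annual heatwave-day count. Reported
#' for the target period, as an anomaly against the baseline annual mean,
#' and per person.
#'
#' @param hw_days the 0/1 field from [detect_heatwaves()].
#' @param pop a [population_grid()] on the same grid.
#' @param group age-group label.
#' @param baseline,target year vectors.
#' @param regions optional [region_table()] for per-HDI aggregation.
#' @return an [indicator_table()] with person-days, person-days anomaly and
#'   days-per-person rows for the group.
#' @export
heatwave_exposure <- function(hw_days, pop, group, baseline = 1986:2005,
                              target = 2021L, regions = NULL) {
  if (!isTRUE(all.equal(pop$lats, hw_days$lats)) ||
      !isTRUE(all.equal(pop$lons, hw_days$lons))) stop("grid mismatch")
  pv <- population_vector(pop, group)
  total <- sum(pv)
  if (total <= 0) stop(sprintf("age group '%s' has zero population", group))
  cnt <- annual_counts(hw_days)
  yrs <- as.integer(rownames(cnt))
  region_of <- if (is.null(regions)) rep("GLOBAL", length(pv)) else
    ifelse(is.na(regions$hdi_group), "GLOBAL", regions$hdi_group)
  pd_region <- function(years) {
    sub <- cnt[yrs %in% years, , drop = FALSE]
    ann <- colMeans(sub)  # mean annual hw days per cell
    by_r <- tapply(ann * pv, region_of, sum)
    c(GLOBAL = sum(ann * pv),
      if (!is.null(regions)) by_r[names(by_r) != "GLOBAL"])
  }
  pd_t <- pd_region(target); pd_b <- pd_region(baseline)
  pop_r <- c(GLOBAL = total,
             if (!is.null(regions)) {
               pr <- tapply(pv, region_of, sum); pr[names(pr) != "GLOBAL"]
             })
  pop_r <- pop_r[names(pd_t)]
  per <- period_label(target)
  g <- function(id) paste0(id, "_", group)
  bind_indicators(
    indicator_table(g("heatwave_person_days"), names(pd_t), per, pd_t, "person-days/yr"),
    indicator_table(g("heatwave_person_days_anomaly"), names(pd_t), per,
                    pd_t - pd_b, "person-days/yr"),
    indicator_table(g("heatwave_days_per_person"), names(pd_t), per,
                    pd_t / pop_r, "days/person/yr"),
    indicator_table(g("heatwave_days_per_person_anomaly"), names(pd_t), per,
                    (pd_t - pd_b) / pop_r, "days/person/yr")
  )
}

#' Sinusoidal hourly temperature between daily Tmin and Tmax
#'
#' Reconstructs the temperature at a local solar `hour` from the daily
#' minimum and maximum, with Tmin at 06:00 and Tmax at 15:00: a quarter-sine
#' rise between 06:00 and 15:00 and a sine fall from 15:00 back to 06:00.
#'
#' @param tmin,tmax numeric (vectors or matrices) daily extrema.
#' @param hour integer hour of day in 0..23.
#' @return numeric of the same shape as `tmin`.
#' @export
hourly_temperature <- function(tmin, tmax, hour) {
  if (hour >= 6 && hour <= 15) {
    frac <- sin(pi * (hour - 6) / 18)  # 0 at 06:00, 1 at 15:00
  } else {
    tau <- (hour - 15) %% 24           # hours since the maximum
    frac <- 1 - sin(pi * tau / 30)     # 1 at 15:00, 0 at 06:00 next day
  }
  tmin + (tmax - tmin) * frac
}

#' Simplified outdoor wet-bulb globe temperature
#'
#' `WBGT = 0.567 T + 0.393 e + 3.94` (degC) with the vapour pressure
#' `e = RH/100 * 6.105 * exp(17.27 T / (237.7 + T))` in hPa: the standard
#' temperature-humidity approximation without wind or radiation terms.
#'
#' @param temp air temperature, degC.
#' @param rh relative humidity, %.
#' @return WBGT in degC, same shape as `temp`.
#' @export
wbgt <- function(temp, rh) {
  if (any(rh < 0 | rh > 100, na.rm = TRUE)) stop("RH outside [0, 100]")
  e <- rh / 100 * 6.105 * exp(17.27 * temp / (237.7 + temp))
  0.567 * temp + 0.393 * e + 3.94
}

#' Annual hours of heat-stress risk per person
#'
#' Reconstructs hourly temperature from daily Tmin/Tmax, computes hourly
#' WBGT with the daily relative humidity, and counts the hours at or above
#' the moderate- and high-risk cut-points, population-weighted per year
#' (globally and per HDI group).
#'
#' @param tmin,tmax,rh daily [climate_field()]s on one grid and time axis.
#' @param pop a [population_grid()] (all-age weights).
#' @param regions optional [region_table()].
#' @param thresholds named vector `c(moderate = , high = )` in degC WBGT.
#' @param baseline,target optional year vectors; when both are given,
#'   anomaly rows (target mean minus baseline mean) are added.
#' @return an [indicator_table()] with `heat_risk_hours_moderate`/`_high`
#'   rows per requested period, units hours/person/yr.
#' @export
wbgt_risk_hours <- function(tmin, tmax, rh, pop, regions = NULL,
                            thresholds = c(moderate = 23, high = 28),
                            baseline = NULL, target = NULL) {
  stop_if_grid_mismatch(tmin, tmax); stop_if_grid_mismatch(tmin, rh)
  tmin_m <- field_matrix(tmin); tmax_m <- field_matrix(tmax)
  rh_m <- field_matrix(rh)
  if (any(rh_m < 0 | rh_m > 100, na.rm = TRUE)) stop("RH outside [0, 100]")
  nmod <- matrix(0L, nrow(tmin_m), ncol(tmin_m))
  nhigh <- nmod
  for (h in 0:23) {
    w <- wbgt(hourly_temperature(tmin_m, tmax_m, h), rh_m)
    nmod <- nmod + (w >= thresholds[["moderate"]])
    nhigh <- nhigh + (w >= thresholds[["high"]])
  }
  pw <- colSums(matrix(pop$counts, nrow = length(pop$age_groups)))
  ann_mod <- rowsum(nmod, tmin$years)   # hours per cell-year
  ann_high <- rowsum(nhigh, tmin$years)
  yrs <- as.integer(rownames(ann_mod))
  rows <- list()
  mean_region <- function(ann, years) {
    v <- colMeans(ann[yrs %in% years, , drop = FALSE])
    global_and_hdi_means(v, pw, regions)
  }
  periods <- if (is.null(target)) list(yrs) else list(target)
  for (p in periods) {
    vm <- mean_region(ann_mod, p); vh <- mean_region(ann_high, p)
    rows <- c(rows, list(
      indicator_table("heat_risk_hours_moderate", names(vm), period_label(p),
                      vm, "hours/person/yr"),
      indicator_table("heat_risk_hours_high", names(vh), period_label(p),
                      vh, "hours/person/yr")))
  }
  if (!is.null(baseline) && !is.null(target)) {
    dm <- mean_region(ann_mod, target) - mean_region(ann_mod, baseline)
    dh <- mean_region(ann_high, target) - mean_region(ann_high, baseline)
    rows <- c(rows, list(
      indicator_table("heat_risk_hours_moderate_anomaly", names(dm),
                      period_label(target), dm, "hours/person/yr"),
      indicator_table("heat_risk_hours_high_anomaly", names(dh),
                      period_label(target), dh, "hours/person/yr")))
  }
  do.call(bind_indicators, rows)
}

#' Sectoral heat-exposure parameters (Hothaps-style)
#'
#' Per-sector logistic work-ability parameters: work ability at a given
#' WBGT is `WA = 0.1 + 0.9 / (1 + (WBGT/alpha1)^alpha2)`, so the loss
#' fraction `1 - WA` rises from 0 towards an 0.9 asymptote and equals 0.45
#' at `WBGT = alpha1`. Outdoor (in-sun) sectors add `sun_wbgt_offset` to
#' WBGT. The shipped defaults are the reference parameterisation for 200 W
#' (services), 300 W (manufacturing) and 400 W (agriculture, construction)
#' workloads, all fully overridable.
#'
#' @param sectors data.frame with columns sector, workload_watts, alpha1,
#'   alpha2, in_sun.
#' @param sun_wbgt_offset degC added to WBGT for in-sun sectors.
#' @param work_hours integer hours of the working day (default 07:00-19:00).
#' @return object of class `hothaps_params`.
#' @export
hothaps_params <- function(sectors = NULL, sun_wbgt_offset = 3,
                           work_hours = 7:18) {
  if (is.null(sectors)) {
    sectors <- data.frame(
      sector = c("agriculture", "construction", "manufacturing", "services"),
      workload_watts = c(400, 400, 300, 200),
      alpha1 = c(32.98, 32.98, 33.49, 34.64),
      alpha2 = c(17.81, 17.81, 22.81, 22.72),
      in_sun = c(TRUE, TRUE, FALSE, FALSE),
      stringsAsFactors = FALSE
    )
  }
  if (any(sectors$alpha1 <= 0) || any(sectors$alpha2 <= 0))
    stop("alpha parameters must be positive")
  structure(list(sectors = sectors, sun_wbgt_offset = sun_wbgt_offset,
                 work_hours = as.integer(work_hours)),
            class = "hothaps_params")
}

#' Logistic work-ability function
#'
#' @param wbgt_val WBGT in degC.
#' @param alpha1 WBGT midpoint (degC), loss fraction 0.45 there.
#' @param alpha2 steepness (dimensionless).
#' @return work ability in [0.1, 1].
#' @export
work_ability <- function(wbgt_val, alpha1, alpha2) {
  if (alpha1 <= 0 || alpha2 <= 0) stop("alpha parameters must be positive")
  0.1 + 0.9 / (1 + (pmax(wbgt_val, 0) / alpha1)^alpha2)
}

#' Potential labour hours lost to heat
#'
#' For every hour of the working day, the lost fraction of work is
#' `1 - WA(WBGT)` (with the in-sun WBGT offset for outdoor sectors); hours
#' lost are the sum over work hours, days and cells of lost fraction times
#' workers. Reported per sector, per HDI group and globally, with the
#' agricultural share of total losses.
#'
#' @param tmin,tmax,rh daily [climate_field()]s.
#' @param pop_working sector-stratified [population_grid()] (e.g. from
#'   [gen_working_population()]).
#' @param params a [hothaps_params()]; sectors must match `pop_working`.
#' @param regions optional [region_table()].
#' @param target years to report (default: all).
#' @return list with `table` (an [indicator_table()]) and `by_country_sector`
#'   (data.frame country, sector, year, hours_lost for the economics stage).
#' @export
labour_hours_lost <- function(tmin, tmax, rh, pop_working,
                              params = hothaps_params(), regions = NULL,
                              target = NULL) {
  stop_if_grid_mismatch(tmin, tmax); stop_if_grid_mismatch(tmin, rh)
  sectors <- params$sectors
  if (!all(pop_working$age_groups %in% sectors$sector))
    stop("sectors in the working population are missing from the parameters")
  tmin_m <- field_matrix(tmin); tmax_m <- field_matrix(tmax)
  rh_m <- field_matrix(rh)
  nt <- nrow(tmin_m); nc <- ncol(tmin_m)
  # loss depends only on the sector alphas and the sun flag, so accumulate
  # the summed hourly loss fraction once per distinct (alpha1, alpha2, sun)
  combos <- unique(sectors[, c("alpha1", "alpha2", "in_sun")])
  loss_sum <- lapply(seq_len(nrow(combos)), function(i) matrix(0, nt, nc))
  for (h in params$work_hours) {
    w <- wbgt(hourly_temperature(tmin_m, tmax_m, h), rh_m)
    for (i in seq_len(nrow(combos))) {
      wi <- if (combos$in_sun[i]) w + params$sun_wbgt_offset else w
      loss_sum[[i]] <- loss_sum[[i]] +
        (1 - work_ability(wi, combos$alpha1[i], combos$alpha2[i]))
    }
  }
  yrs_all <- sort(unique(tmin$years))
  if (is.null(target)) target <- yrs_all
  region_of <- if (is.null(regions)) rep(NA_character_, nc) else regions$hdi_group
  country_of <- if (is.null(regions)) rep(NA_character_, nc) else regions$country_code

  recs <- list()
  for (s in seq_len(nrow(sectors))) {
    grp <- sectors$sector[s]
    if (!grp %in% pop_working$age_groups) next
    ci <- which(combos$alpha1 == sectors$alpha1[s] &
                  combos$alpha2 == sectors$alpha2[s] &
                  combos$in_sun == sectors$in_sun[s])
    ann <- rowsum(loss_sum[[ci]], tmin$years)  # lost hours per cell-year, per worker
    workers <- population_vector(pop_working, grp)
    lost <- sweep(ann, 2L, workers, "*")       # [year, cell] hours lost
    yrs <- as.integer(rownames(ann))
    keep <- yrs %in% target
    recs[[grp]] <- data.frame(
      year = rep(yrs[keep], times = nc),
      cell = rep(seq_len(nc), each = sum(keep)),
      sector = grp,
      hours = as.vector(lost[keep, , drop = FALSE]),
      stringsAsFactors = FALSE
    )
  }
  long <- do.call(rbind, recs)
  long$hdi <- region_of[long$cell]
  long$country <- country_of[long$cell]

  per <- period_label(target)
  tot_sector <- tapply(long$hours, long$sector, sum) / length(target)
  total <- sum(tot_sector)
  rows <- list(
    indicator_table(paste0("labour_hours_lost_", names(tot_sector)), "GLOBAL",
                    per, tot_sector, "hours/yr"),
    indicator_table("labour_hours_lost_total", "GLOBAL", per, total, "hours/yr"),
    indicator_table("labour_hours_lost_agriculture_share", "GLOBAL", per,
                    if (total > 0) tot_sector[["agriculture"]] / total else NA_real_,
                    "fraction")
  )
  if (!is.null(regions)) {
    by_hdi <- tapply(long$hours, long$hdi, sum) / length(target)
    ag_hdi <- tapply(long$hours[long$sector == "agriculture"],
                     long$hdi[long$sector == "agriculture"], sum) / length(target)
    rows <- c(rows, list(
      indicator_table("labour_hours_lost_total", names(by_hdi), per, by_hdi, "hours/yr"),
      indicator_table("labour_hours_lost_agriculture_share", names(ag_hdi), per,
                      ag_hdi / by_hdi[names(ag_hdi)], "fraction")))
  }
  with_country <- long[!is.na(long$country), , drop = FALSE]
  by_cs <- if (nrow(with_country)) {
    a <- stats::aggregate(hours ~ country + sector + year, data = with_country,
                          FUN = sum)
    names(a)[names(a) == "hours"] <- "hours_lost"
    a
  } else {
    data.frame(country = character(), sector = character(),
               year = integer(), hours_lost = numeric())
  }
  list(table = do.call(bind_indicators, rows), by_country_sector = by_cs)
}

#' Heat-mortality exposure-response parameters
#'
#' A single log-linear exposure-response slope above a percentile threshold:
#' daily relative risk `RR = exp(beta_mort * max(0, T - threshold))`. The
#' default slope (0.05 per degC for the 65+ group above the 95th percentile)
#' is configuration, not an asserted value.
#'
#' @param threshold_percentile percentile for the temperature threshold.
#' @param beta_mort log relative risk per degC above threshold (>= 0).
#' @param baseline_deaths named numeric, annual baseline deaths in the 65+
#'   group per country.
#' @param residual_life_expectancy named numeric or scalar, years per death.
#' @return object of class `mortality_er_params`.
#' @export
mortality_er_params <- function(threshold_percentile = 0.95, beta_mort = 0.05,
                                baseline_deaths = NULL,
                                residual_life_expectancy = 12) {
  if (beta_mort < 0) stop("beta_mort must be >= 0")
  if (!is.null(baseline_deaths) && any(baseline_deaths < 0))
    stop("baseline_deaths must be >= 0")
  structure(list(threshold_percentile = threshold_percentile,
                 beta_mort = beta_mort, baseline_deaths = baseline_deaths,
                 residual_life_expectancy = residual_life_expectancy),
            class = "mortality_er_params")
}

#' Heat-attributable mortality and years of life lost
#'
#' Daily attributable fraction `AF = 1 - 1/RR` with
#' `RR = exp(beta * max(0, T - threshold))`; attributable deaths are the sum
#' over days of AF (population-weighted over a country's cells) times the
#' daily baseline deaths (annual deaths / 365). YLL multiplies by residual
#' life expectancy. When two periods are given, the relative change in mean
#' annual attributable deaths is reported.
#'
#' @param tmean daily mean-temperature [climate_field()].
#' @param clim percentile climatology for the threshold (same machinery as
#'   heatwaves).
#' @param pop65 [population_grid()]; the "65plus" group supplies weights.
#' @param regions [region_table()] mapping cells to countries.
#' @param params a [mortality_er_params()] with per-country baseline deaths.
#' @param period1,period2 optional year vectors for the percentage change.
#' @return list with `table` (an [indicator_table()]) and `yll_by_country`
#'   (named vector of mean annual YLL over `period2` or the full record).
#' @export
heat_attributable_mortality <- function(tmean, clim, pop65, regions, params,
                                        period1 = NULL, period2 = NULL) {
  if (params$beta_mort < 0) stop("beta_mort must be >= 0")
  dT <- pmax(field_matrix(tmean) - threshold_matrix(clim, tmean), 0)
  af <- 1 - exp(-params$beta_mort * dT)  # 1 - 1/RR
  w65 <- population_vector(pop65, "65plus")
  countries <- sort(unique(stats::na.omit(regions$country_code)))
  yrs <- sort(unique(tmean$years))
  deaths <- matrix(0, length(yrs), length(countries),
                   dimnames = list(as.character(yrs), countries))
  for (co in countries) {
    cells <- which(!is.na(regions$country_code) & regions$country_code == co)
    w <- w65[cells]
    if (sum(w) <= 0) { deaths[, co] <- NA_real_; next }
    af_day <- as.vector(af[, cells, drop = FALSE] %*% w) / sum(w)
    ann_deaths <- if (is.null(params$baseline_deaths)) 0 else
      params$baseline_deaths[[co]]
    daily_af_sum <- rowsum(af_day, tmean$years)
    deaths[, co] <- daily_af_sum * ann_deaths / DAYS_PER_YEAR
  }
  rle_of <- function(co) {
    r <- params$residual_life_expectancy
    if (length(r) > 1L || !is.null(names(r))) r[[co]] else r
  }
  yll <- sweep(deaths, 2L, vapply(countries, rle_of, numeric(1)), "*")
  p2 <- if (is.null(period2)) yrs else period2
  mean_p <- function(m, p) colMeans(m[as.character(intersect(yrs, p)), , drop = FALSE])
  d2 <- mean_p(deaths, p2); y2 <- mean_p(yll, p2)
  per <- period_label(p2)
  rows <- list(
    indicator_table("heat_attributable_deaths", names(d2), per, d2, "deaths/yr"),
    indicator_table("heat_attributable_deaths", "GLOBAL", per, sum(d2), "deaths/yr"),
    indicator_table("heat_attributable_yll", names(y2), per, y2, "years/yr"),
    indicator_table("heat_attributable_yll", "GLOBAL", per, sum(y2), "years/yr")
  )
  if (!is.null(period1) && !is.null(period2)) {
    d1 <- sum(mean_p(deaths, period1)); d2s <- sum(d2)
    chg <- if (d1 > 0) 100 * (d2s - d1) / d1 else NA_real_
    rows <- c(rows, list(indicator_table(
      "heat_attributable_deaths_pct_change", "GLOBAL",
      paste(period_label(period1), period_label(period2), sep = " vs "),
      chg, "%")))
  }
  list(table = do.call(bind_indicators, rows), yll_by_country = y2)
}
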