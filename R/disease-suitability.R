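# Climatic suitability for infectious disease transmission: the
# vectorial-capacity basic reproduction number for Aedes-borne arboviruses,
# threshold-based malaria transmission months, and coastal Vibrio
# suitability from sea-surface temperature and salinity.

briere_response <- function(temp, c0, tmin, tmax) {
  ifelse(temp > tmin & temp < tmax,
         c0 * temp * (temp - tmin) * sqrt(pmax(tmax - temp, 0)), 0)
}

quadratic_response <- function(temp, c0, tmin, tmax) {
  pmax(c0 * (temp - tmin) * (tmax - temp), 0)
}

#' Arbovirus R0 parameters
#'
#' Temperature-response coefficients for the vectorial-capacity basic
#' reproduction number. The shipped default coefficient file
#' (`dengue_coefficients_aegypti.csv`) carries the widely used Aedes
#' aegypti/dengue thermal-response parameterisation (Briere responses for
#' biting rate, transmission probabilities and parasite development rate; a
#' concave quadratic for adult lifespan); any species can be substituted by
#' supplying another file with the same `function,term,value` layout.
#'
#' @param coef_file CSV path; default is the file shipped with the package.
#' @param r human recovery rate per day (default 0.2).
#' @param m0 vector-per-person density ceiling of the rainfall response.
#' @param p_half monthly rainfall (mm) at which vector density saturates.
#' @param min_lifespan floor on adult lifespan in days (keeps the mortality
#'   rate finite outside the viable temperature range).
#' @return object of class `dengue_params`.
#' @export
dengue_params <- function(coef_file = NULL, r = 0.2, m0 = 2, p_half = 80,
                          min_lifespan = 0.01) {
  if (is.null(coef_file))
    coef_file <- system.file("extdata", "dengue_coefficients_aegypti.csv",
                             package = "climind")
  df <- utils::read.csv(coef_file, stringsAsFactors = FALSE)
  fun <- function(name) {
    sub <- df[df[["function."]] == name | df[[1L]] == name, ]
    form <- sub$value[sub$term == "form"]
    cf <- as.numeric(sub$value[sub$term == "c"])
    t0 <- as.numeric(sub$value[sub$term == "tmin"])
    t1 <- as.numeric(sub$value[sub$term == "tmax"])
    list(form = form, c = cf, tmin = t0, tmax = t1)
  }
  structure(list(biting_rate = fun("biting_rate"),
                 prob_vh = fun("prob_vector_to_human"),
                 prob_hv = fun("prob_human_to_vector"),
                 lifespan = fun("lifespan"),
                 pdr = fun("pdr"),
                 r = r, m0 = m0, p_half = p_half,
                 min_lifespan = min_lifespan),
            class = "dengue_params")
}

eval_response <- function(spec, temp) {
  switch(spec$form,
         briere = briere_response(temp, spec$c, spec$tmin, spec$tmax),
         quadratic = quadratic_response(temp, spec$c, spec$tmin, spec$tmax),
         stop("unknown response form: ", spec$form))
}

#' Temperature- and rainfall-dependent arbovirus R0
#'
#' The vectorial-capacity form
#' `R0 = sqrt( m(P) a(T)^2 b(T) c(T) exp(-mu(T) EIP(T)) / (mu(T) r) )`
#' with biting rate a, transmission probabilities b and c (clipped to
#' [0, 1]), mosquito mortality `mu = 1/lifespan`, extrinsic incubation
#' period `EIP = 1/PDR`, and relative vector density
#' `m = m0 * min(P/p_half, 1)` saturating in monthly rainfall.
#'
#' @param temp temperature, degC (any shape).
#' @param precip monthly rainfall, mm (same shape or scalar).
#' @param params a [dengue_params()].
#' @return R0, same shape as `temp`; non-negative.
#' @export
dengue_r0 <- function(temp, precip, params = dengue_params()) {
  a <- eval_response(params$biting_rate, temp)
  b <- pmin(pmax(eval_response(params$prob_vh, temp), 0), 1)
  cc <- pmin(pmax(eval_response(params$prob_hv, temp), 0), 1)
  lifespan <- pmax(eval_response(params$lifespan, temp), params$min_lifespan)
  mu <- 1 / lifespan
  if (any(mu <= 0)) stop("mosquito mortality rate must be positive")
  pdr <- eval_response(params$pdr, temp)
  surv <- ifelse(pdr > 0, exp(-mu / pdr), 0)  # exp(-mu * EIP)
  m <- params$m0 * pmin(precip / params$p_half, 1)
  sqrt(m * a^2 * b * cc * surv / (mu * params$r))
}

#' Decadal change in arbovirus transmission suitability
#'
#' Monthly R0 from [dengue_r0()], averaged over each decade's months with
#' population weighting over cells; reports the decadal means, the relative
#' change, and the transmission-season length (mean months per year with
#' R0 > 1, population-weighted).
#'
#' @param tmean_monthly,precip_monthly `monthly_field`s on one grid.
#' @param pop a [population_grid()] (all-age weights).
#' @param params a [dengue_params()].
#' @param baseline_decade,target_decade year vectors.
#' @return an [indicator_table()].
#' @export
dengue_r0_suitability <- function(tmean_monthly, precip_monthly, pop,
                                  params = dengue_params(),
                                  baseline_decade, target_decade) {
  if (!identical(tmean_monthly$years, precip_monthly$years))
    stop("monthly fields are not aligned")
  r0 <- dengue_r0(monthly_matrix(tmean_monthly), monthly_matrix(precip_monthly),
                  params)
  yrs <- tmean_monthly$years
  pw <- colSums(matrix(pop$counts, nrow = length(pop$age_groups)))
  decade_stats <- function(years) {
    sub <- r0[yrs %in% years, , drop = FALSE]
    cell_mean <- colMeans(sub)
    months_gt1 <- colSums(sub > 1) / length(unique(yrs[yrs %in% years]))
    c(mean = unname(weighted_regional_mean(cell_mean, pw, rep("G", length(pw)))),
      season = unname(weighted_regional_mean(months_gt1, pw, rep("G", length(pw)))))
  }
  b <- decade_stats(baseline_decade); t <- decade_stats(target_decade)
  chg <- if (b[["mean"]] > 0) 100 * (t[["mean"]] - b[["mean"]]) / b[["mean"]] else NA_real_
  pers <- c(period_label(baseline_decade), period_label(target_decade))
  keep <- !duplicated(pers)
  vs <- paste(pers[1L], pers[2L], sep = " vs ")
  bind_indicators(
    indicator_table("dengue_r0_mean", "GLOBAL", pers[keep],
                    c(b[["mean"]], t[["mean"]])[keep], "dimensionless"),
    indicator_table("dengue_r0_change", "GLOBAL", vs, chg, "%"),
    indicator_table("dengue_transmission_months", "GLOBAL", pers[keep],
                    c(b[["season"]], t[["season"]])[keep], "months/yr")
  )
}

#' Malaria suitability thresholds
#'
#' A month is suitable for transmission when `t_min <= T < t_max` (lower
#' bound inclusive, upper exclusive), monthly rainfall `P >= precip_min`,
#' relative humidity `RH >= rh_min`, and (when a mask is given) the cell's
#' land class is in `land_class_mask`.
#'
#' @param t_min,t_max temperature window, degC (defaults 18, 32).
#' @param precip_min minimum monthly rainfall, mm (default 80).
#' @param rh_min minimum relative humidity, % (default 60).
#' @param highland_cutoff_m highland elevation cut, metres (default 1500).
#' @param land_class_mask optional character vector of suitable land classes.
#' @return object of class `malaria_thresholds`.
#' @export
malaria_thresholds <- function(t_min = 18, t_max = 32, precip_min = 80,
                               rh_min = 60, highland_cutoff_m = 1500,
                               land_class_mask = NULL) {
  if (t_min >= t_max) stop("t_min must be below t_max")
  if (precip_min < 0) stop("precip_min must be >= 0")
  structure(list(t_min = t_min, t_max = t_max, precip_min = precip_min,
                 rh_min = rh_min, highland_cutoff_m = highland_cutoff_m,
                 land_class_mask = land_class_mask),
            class = "malaria_thresholds")
}

#' Months per year suitable for malaria transmission
#'
#' Counts suitable months per cell-year under [malaria_thresholds()],
#' reported as the area-weighted mean over land cells (and over highland
#' cells at or above the elevation cut), per decade and as relative change.
#'
#' @param tmean_monthly,precip_monthly,rh_monthly `monthly_field`s.
#' @param regions a [region_table()].
#' @param thr a [malaria_thresholds()].
#' @param baseline_decade,target_decade year vectors.
#' @return an [indicator_table()].
#' @export
malaria_suitable_months <- function(tmean_monthly, precip_monthly, rh_monthly,
                                    regions, thr = malaria_thresholds(),
                                    baseline_decade, target_decade) {
  tm <- monthly_matrix(tmean_monthly)
  pm <- monthly_matrix(precip_monthly)
  hm <- monthly_matrix(rh_monthly)
  suit <- tm >= thr$t_min & tm < thr$t_max & pm >= thr$precip_min & hm >= thr$rh_min
  if (!is.null(thr$land_class_mask)) {
    ok_class <- !is.na(regions$land_class) &
      regions$land_class %in% thr$land_class_mask
    suit <- sweep(suit, 2L, ok_class, "&")
  }
  yrs <- tmean_monthly$years
  w <- area_weights(tmean_monthly$lats, tmean_monthly$lons)
  land <- regions$is_land
  highland <- land & !is.na(regions$elevation_m) &
    regions$elevation_m >= thr$highland_cutoff_m
  months_per_year <- function(years, mask) {
    if (!any(mask)) return(NA_real_)
    sub <- suit[yrs %in% years, mask, drop = FALSE]
    per_cell <- colSums(sub) / length(unique(yrs[yrs %in% years]))
    sum(w[mask] * per_cell) / sum(w[mask])
  }
  out <- c(all_b = months_per_year(baseline_decade, land),
           all_t = months_per_year(target_decade, land),
           high_b = months_per_year(baseline_decade, highland),
           high_t = months_per_year(target_decade, highland))
  rel <- function(b, t) if (!is.na(b) && b > 0) 100 * (t - b) / b else NA_real_
  pb <- period_label(baseline_decade); pt <- period_label(target_decade)
  keep <- !duplicated(c(pb, pt))
  vs <- paste(pb, pt, sep = " vs ")
  bind_indicators(
    indicator_table("malaria_suitable_months", "GLOBAL", c(pb, pt)[keep],
                    out[c("all_b", "all_t")][keep], "months/yr"),
    indicator_table("malaria_suitable_months_highland", "GLOBAL", c(pb, pt)[keep],
                    out[c("high_b", "high_t")][keep], "months/yr"),
    indicator_table("malaria_suitable_months_change", "GLOBAL", vs,
                    rel(out[["all_b"]], out[["all_t"]]), "%"),
    indicator_table("malaria_suitable_months_highland_change", "GLOBAL", vs,
                    rel(out[["high_b"]], out[["high_t"]]), "%")
  )
}

#' Vibrio coastal suitability thresholds
#'
#' A day is suitable when sea-surface temperature is at least `sst_min` and
#' salinity at most `sss_max` (brackish); a coastal cell-year is suitable
#' when it contains at least `min_run_days` consecutive suitable days.
#'
#' @param sst_min minimum SST, degC (default 18).
#' @param sss_max maximum salinity, psu (default 28).
#' @param min_run_days minimum consecutive suitable days (default 5).
#' @param latitude_band optional length-2 vector restricting the coastal
#'   cells, e.g. `c(40, 70)`.
#' @return object of class `vibrio_thresholds`.
#' @export
vibrio_thresholds <- function(sst_min = 18, sss_max = 28, min_run_days = 5L,
                              latitude_band = NULL) {
  if (min_run_days < 1L) stop("min_run_days must be >= 1")
  structure(list(sst_min = sst_min, sss_max = sss_max,
                 min_run_days = as.integer(min_run_days),
                 latitude_band = latitude_band),
            class = "vibrio_thresholds")
}

#' Fraction of coastal cells suitable for Vibrio pathogens
#'
#' Per period: the mean over years of the cosine-latitude-weighted fraction
#' of coastal cells that are suitable that year (at least `min_run_days`
#' consecutive days with SST >= sst_min and SSS <= sss_max, runs evaluated
#' within the year). Reports both period values and the change in
#' percentage points.
#'
#' @param sst_daily,sss_daily daily [climate_field()]s.
#' @param regions a [region_table()].
#' @param thr a [vibrio_thresholds()].
#' @param period1,period2 year vectors.
#' @return an [indicator_table()].
#' @export
vibrio_coastal_suitability <- function(sst_daily, sss_daily, regions,
                                       thr = vibrio_thresholds(),
                                       period1, period2) {
  stop_if_grid_mismatch(sst_daily, sss_daily)
  coast <- regions$is_coastal
  if (!is.null(thr$latitude_band))
    coast <- coast & regions$lat >= thr$latitude_band[1L] &
      regions$lat <= thr$latitude_band[2L]
  if (!any(coast)) stop("no coastal cells in the requested latitude band")
  suit_day <- (field_matrix(sst_daily) >= thr$sst_min) &
    (field_matrix(sss_daily) <= thr$sss_max)
  suit_day <- suit_day[, coast, drop = FALSE]
  yrs <- sst_daily$years
  uy <- sort(unique(yrs))
  cell_year <- matrix(FALSE, length(uy), ncol(suit_day))
  for (yi in seq_along(uy)) {
    rows <- yrs == uy[yi]
    cell_year[yi, ] <- apply(suit_day[rows, , drop = FALSE], 2L, function(x)
      any(flag_min_runs(x, thr$min_run_days)))
  }
  w <- area_weights(sst_daily$lats, sst_daily$lons)[coast]
  frac <- as.vector(cell_year %*% w) / sum(w)
  period_frac <- function(p) mean(frac[uy %in% p])
  f1 <- period_frac(period1); f2 <- period_frac(period2)
  p1 <- period_label(period1); p2 <- period_label(period2)
  keep <- !duplicated(c(p1, p2))
  bind_indicators(
    indicator_table("vibrio_coastal_suitability", "GLOBAL", c(p1, p2)[keep],
                    100 * c(f1, f2)[keep], "%"),
    indicator_table("vibrio_coastal_suitability_change_pp", "GLOBAL",
                    paste(p1, p2, sep = " vs "), 100 * (f2 - f1),
                    "percentage points")
  )
}
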