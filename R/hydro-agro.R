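# Drought and agro-climate indicators: monthly aggregation, Thornthwaite
# potential evapotranspiration, the SPEI with per-calendar-month log-logistic
# L-moment calibration, extreme-drought area, growing-degree-day crop season
# lengths and coastal SST change.

#' Aggregate a daily field to calendar months
#'
#' @param field a daily [climate_field()].
#' @param fun "mean" (temperatures) or "sum" (precipitation totals).
#' @return object of class `monthly_field`: per-month values array
#'   [n_month, n_lat, n_lon] with parallel `years` and `months` vectors.
#' @export
monthly_climate <- function(field, fun = c("mean", "sum")) {
  fun <- match.arg(fun)
  mo <- doy_to_month(field$doys)
  key <- field$years * 100L + mo
  m <- field_matrix(field)
  agg <- rowsum(m, key)
  if (fun == "mean") agg <- agg / as.vector(table(key))
  ukey <- as.integer(rownames(agg))
  nlat <- length(field$lats); nlon <- length(field$lons)
  arr <- array(agg, dim = c(nrow(agg), nlat, nlon))
  structure(list(variable = field$variable, units = field$units,
                 years = ukey %/% 100L, months = ukey %% 100L,
                 lats = field$lats, lons = field$lons, values = arr),
            class = "monthly_field")
}

monthly_matrix <- function(mf) {
  m <- mf$values
  dim(m) <- c(length(mf$years), length(mf$lats) * length(mf$lons))
  m
}

# mean day length (hours) at latitude `lat_deg` for the mid-day of `month`
day_length_hours <- function(lat_deg, month) {
  mid <- NOLEAP_MONTH_STARTS[month] + NOLEAP_MONTH_LENGTHS[month] / 2
  decl <- 0.409 * sin(2 * pi * mid / DAYS_PER_YEAR - 1.39)
  cosw <- pmin(pmax(-tan(lat_deg * pi / 180) * tan(decl), -1), 1)
  24 / pi * acos(cosw)
}

#' Thornthwaite monthly potential evapotranspiration
#'
#' Temperature-only PET: the annual heat index is
#' `I = sum_m (max(T_m, 0)/5)^1.514`, the exponent
#' `a = 6.75e-7 I^3 - 7.71e-5 I^2 + 1.792e-2 I + 0.49239`, and
#' `PET_m = 16 (10 max(T_m, 0)/I)^a * C_m` mm, with the day-length/day-count
#' correction `C_m = (L/12)(N/30)`. PET is 0 for months at or below 0 degC,
#' and identically 0 where the heat index is 0.
#'
#' @param tmean_monthly a `monthly_field` of mean temperature (degC).
#' @param correction "daylength" for the latitude-dependent `C_m`, or
#'   "none" to take `C_m = 1` everywhere.
#' @return a `monthly_field` of PET in mm/month.
#' @export
thornthwaite_pet <- function(tmean_monthly, correction = c("daylength", "none")) {
  correction <- match.arg(correction)
  mf <- tmean_monthly
  m <- monthly_matrix(mf)
  tp <- pmax(m, 0)
  years <- mf$years
  # annual heat index per (year, cell)
  hi <- rowsum((tp / 5)^1.514, years)
  uy <- as.integer(rownames(hi))
  I_full <- hi[match(years, uy), , drop = FALSE]
  a <- 6.75e-7 * I_full^3 - 7.71e-5 * I_full^2 + 1.792e-2 * I_full + 0.49239
  pet <- matrix(0, nrow(m), ncol(m))
  pos <- I_full > 0 & tp > 0
  pet[pos] <- 16 * (10 * tp[pos] / I_full[pos])^a[pos]
  if (correction == "daylength") {
    ct <- cell_table(mf$lats, mf$lons)
    Cm <- outer(mf$months, seq_len(nrow(ct)), function(mo, k) {
      day_length_hours(ct$lat[k], mo) / 12 * (NOLEAP_MONTH_LENGTHS[mo] / 30)
    })
    pet <- pet * Cm
  }
  arr <- array(pet, dim = dim(mf$values))
  structure(list(variable = "pet", units = "mm", years = mf$years,
                 months = mf$months, lats = mf$lats, lons = mf$lons,
                 values = arr),
            class = "monthly_field")
}

#' SPEI parameters
#'
#' @param scale_months accumulation scale (default 6, i.e. SPEI6).
#' @param extreme_threshold extreme-drought cut-point (default -1.6).
#' @param calibration_years optional length-2 year range used to fit the
#'   distribution; default NULL uses the full record.
#' @param reference_decade,comparison_decade year vectors for the
#'   extreme-drought-area change.
#' @return object of class `spei_params`.
#' @export
spei_params <- function(scale_months = 6L, extreme_threshold = -1.6,
                        calibration_years = NULL,
                        reference_decade = NULL, comparison_decade = NULL) {
  if (scale_months < 1L) stop("scale_months must be >= 1")
  if (extreme_threshold >= 0) stop("extreme_threshold must be negative")
  structure(list(scale_months = as.integer(scale_months),
                 extreme_threshold = extreme_threshold,
                 calibration_years = calibration_years,
                 reference_decade = reference_decade,
                 comparison_decade = comparison_decade),
            class = "spei_params")
}

# unbiased sample probability-weighted moments b_s = E[X (1-F)^s], s = 0,1,2
pwm_unbiased <- function(x) {
  x <- sort(x)
  n <- length(x)
  i <- seq_len(n)
  b0 <- mean(x)
  b1 <- sum(x * (n - i)) / (n * (n - 1))
  b2 <- sum(x * (n - i) * (n - i - 1)) / (n * (n - 1) * (n - 2))
  c(b0 = b0, b1 = b1, b2 = b2)
}

#' Fit a three-parameter log-logistic distribution by L-moments
#'
#' CDF `F(x) = (1 + (scale/(x - location))^shape)^-1` for x > location.
#' Parameters follow from the unbiased probability-weighted moments:
#' `shape = (2 b1 - b0)/(6 b1 - b0 - 6 b2)`,
#' `scale = (b0 - 2 b1) shape / (G(1 + 1/shape) G(1 - 1/shape))`,
#' `location = b0 - scale * G(1 + 1/shape) G(1 - 1/shape)`.
#' Samples whose L-skewness is non-positive cannot carry this
#' (right-skewed) distribution; the fit returns NA parameters then.
#'
#' @param x numeric sample (n >= 8 recommended).
#' @return named vector c(scale, shape, location), NA on a degenerate or
#'   incompatible sample.
#' @export
fit_loglogistic <- function(x) {
  x <- x[!is.na(x)]
  fail <- c(scale = NA_real_, shape = NA_real_, location = NA_real_)
  if (length(x) < 4L || stats::sd(x) == 0) return(fail)
  b <- pwm_unbiased(x)
  denom <- 6 * b["b1"] - b["b0"] - 6 * b["b2"]
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) return(fail)
  shape <- unname((2 * b["b1"] - b["b0"]) / denom)
  if (!is.finite(shape) || shape <= 1.0001) return(fail)
  g <- gamma(1 + 1 / shape) * gamma(1 - 1 / shape)
  scale <- unname((b["b0"] - 2 * b["b1"]) * shape / g)
  if (!is.finite(scale) || scale <= 0) return(fail)
  location <- unname(b["b0"] - scale * g)
  c(scale = scale, shape = shape, location = location)
}

#' Log-logistic distribution function
#' @param q quantiles.
#' @param scale,shape,location parameters as in [fit_loglogistic()].
#' @return cumulative probabilities.
#' @export
ploglogistic <- function(q, scale, shape, location = 0) {
  p <- numeric(length(q))
  p[is.na(q)] <- NA_real_
  pos <- !is.na(q) & q > location
  p[pos] <- 1 / (1 + (scale / (q[pos] - location))^shape)
  p
}

#' Log-logistic random deviates
#' @param n sample size.
#' @param scale,shape,location parameters as in [fit_loglogistic()].
#' @return numeric vector.
#' @export
rloglogistic <- function(n, scale, shape, location = 0) {
  u <- stats::runif(n)
  location + scale * (u / (1 - u))^(1 / shape)
}

#' Rational approximation of the standard-normal quantile
#'
#' The Abramowitz-Stegun rational approximation conventionally used to
#' transform fitted probabilities into SPEI values (absolute error below
#' 4.5e-4).
#'
#' @param p probabilities in (0, 1).
#' @return approximate standard-normal quantiles.
#' @export
std_normal_quantile <- function(p) {
  c0 <- 2.515517; c1 <- 0.802853; c2 <- 0.010328
  d1 <- 1.432788; d2 <- 0.189269; d3 <- 0.001308
  lower <- p < 0.5
  pp <- ifelse(lower, p, 1 - p)
  pp <- pmax(pp, 1e-300)
  w <- sqrt(-2 * log(pp))
  z <- w - (c0 + c1 * w + c2 * w^2) / (1 + d1 * w + d2 * w^2 + d3 * w^3)
  ifelse(lower, -z, z)
}

#' Standardised precipitation-evapotranspiration index
#'
#' The climatic water balance `D = P - PET` is accumulated over
#' `scale_months` (months before the first full window are missing), then,
#' per grid cell and calendar month, a three-parameter log-logistic
#' distribution is fitted by L-moments to the calibration sample and the
#' fitted probabilities are mapped through the standard-normal quantile
#' approximation. Cells/months whose calibration sample is degenerate (zero
#' variance) or incompatible with the distribution yield missing values.
#' Samples with non-positive L-skewness are fitted on the reflected sample
#' (the index then enters through the matching upper tail), preserving the
#' standardisation.
#'
#' @param precip_monthly `monthly_field` of precipitation totals (mm).
#' @param pet_monthly `monthly_field` of PET (mm), same axes.
#' @param params a [spei_params()].
#' @return a `monthly_field` of SPEI values (dimensionless).
#' @export
spei <- function(precip_monthly, pet_monthly, params = spei_params()) {
  if (!identical(precip_monthly$years, pet_monthly$years) ||
      !identical(precip_monthly$months, pet_monthly$months))
    stop("precipitation and PET monthly axes differ")
  D <- monthly_matrix(precip_monthly) - monthly_matrix(pet_monthly)
  k <- params$scale_months
  nm <- nrow(D)
  X <- apply(D, 2L, function(d) {
    cs <- cumsum(d)
    c(rep(NA_real_, k - 1L), cs[k:nm] - c(0, cs)[(k:nm) - k + 1L])
  })
  yrs <- precip_monthly$years
  cal <- if (is.null(params$calibration_years)) rep(TRUE, nm) else
    yrs >= params$calibration_years[1L] & yrs <= params$calibration_years[2L]
  if (sum(cal) < 20L * 12L)
    warning("SPEI calibration period shorter than 20 years of months")
  out <- matrix(NA_real_, nm, ncol(D))
  mos <- precip_monthly$months
  for (mo in 1:12) {
    rows <- which(mos == mo)
    cal_rows <- rows[cal[rows]]
    for (cell in seq_len(ncol(D))) {
      xc <- X[cal_rows, cell]
      xc <- xc[!is.na(xc)]
      if (length(xc) < 8L || stats::sd(xc) == 0) next
      reflect <- FALSE
      fit <- fit_loglogistic(xc)
      if (anyNA(fit)) {                 # non-positive L-skewness: reflect
        fit <- fit_loglogistic(-xc)
        reflect <- TRUE
        if (anyNA(fit)) next
      }
      xall <- X[rows, cell]
      p <- if (reflect) {
        1 - ploglogistic(-xall, fit["scale"], fit["shape"], fit["location"])
      } else {
        ploglogistic(xall, fit["scale"], fit["shape"], fit["location"])
      }
      p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
      out[rows, cell] <- std_normal_quantile(p)
      out[rows, cell][is.na(xall)] <- NA_real_
    }
  }
  arr <- array(out, dim = dim(precip_monthly$values))
  structure(list(variable = "spei", units = "dimensionless",
                 years = precip_monthly$years, months = precip_monthly$months,
                 lats = precip_monthly$lats, lons = precip_monthly$lons,
                 values = arr, scale_months = k),
            class = "monthly_field")
}

#' Land area affected by extreme drought
#'
#' A cell-year is "affected" when any month of that year has
#' SPEI <= `extreme_threshold`. The affected fraction of land area uses
#' cosine-latitude weights over land cells; the decadal value is the mean of
#' annual fractions, and the change between decades is reported in
#' percentage points and in relative percent.
#'
#' @param spei_field `monthly_field` from [spei()].
#' @param regions [region_table()] (land mask).
#' @param params a [spei_params()] with reference/comparison decades.
#' @return an [indicator_table()].
#' @export
extreme_drought_area <- function(spei_field, regions, params) {
  m <- monthly_matrix(spei_field)
  yrs <- spei_field$years
  land <- regions$is_land
  w <- area_weights(spei_field$lats, spei_field$lons)
  uy <- sort(unique(yrs))
  frac <- vapply(uy, function(y) {
    sub <- m[yrs == y, , drop = FALSE]
    hit <- apply(sub, 2L, function(x) {
      if (all(is.na(x))) NA else any(x <= params$extreme_threshold, na.rm = TRUE)
    })
    ok <- land & !is.na(hit)
    if (!any(ok)) return(NA_real_)
    sum(w[ok] * hit[ok]) / sum(w[ok])
  }, numeric(1))
  names(frac) <- uy
  rows <- list(indicator_table("extreme_drought_area", "GLOBAL",
                               as.character(uy), 100 * frac, "%"))
  ref <- params$reference_decade; cmp <- params$comparison_decade
  if (!is.null(ref) && !is.null(cmp)) {
    fr <- mean(frac[as.character(intersect(uy, ref))], na.rm = TRUE)
    fc <- mean(frac[as.character(intersect(uy, cmp))], na.rm = TRUE)
    rows <- c(rows, list(
      indicator_table("extreme_drought_area_decadal", "GLOBAL",
                      c(period_label(ref), period_label(cmp)),
                      100 * c(fr, fc), "%"),
      indicator_table("extreme_drought_area_change_pp", "GLOBAL",
                      paste(period_label(ref), period_label(cmp), sep = " vs "),
                      100 * (fc - fr), "percentage points"),
      indicator_table("extreme_drought_area_change_rel", "GLOBAL",
                      paste(period_label(ref), period_label(cmp), sep = " vs "),
                      if (fr > 0) 100 * (fc - fr) / fr else NA_real_, "%")))
  }
  do.call(bind_indicators, rows)
}

#' Crop calendar and thermal-time parameters
#'
#' Sowing days are fixed per hemisphere; daily growing-degree-days are
#' `clip(T, t_base, t_cap) - t_base` (zero at or below the base
#' temperature). Defaults are documented placeholders for the four staple
#' crops and fully overridable.
#'
#' @param crops data.frame with columns crop, sowing_doy_nh, sowing_doy_sh,
#'   gdd_requirement, t_base, t_cap.
#' @return object of class `crop_params`.
#' @export
crop_params <- function(crops = NULL) {
  if (is.null(crops)) {
    crops <- data.frame(
      crop = c("maize", "rice", "winter_wheat", "spring_wheat"),
      sowing_doy_nh = c(121L, 152L, 274L, 91L),
      sowing_doy_sh = c(305L, 335L, 91L, 274L),
      gdd_requirement = c(1500, 2000, 1700, 1300),
      t_base = c(8, 10, 0, 0),
      t_cap = c(30, 35, 26, 26),
      stringsAsFactors = FALSE
    )
  }
  if (any(crops$t_cap <= crops$t_base)) stop("t_cap must exceed t_base")
  if (any(crops$gdd_requirement <= 0)) stop("gdd_requirement must be positive")
  structure(list(crops = crops), class = "crop_params")
}

#' Growing-season length from thermal time
#'
#' Starting at the hemisphere's sowing day each year, counts the days
#' (sowing day inclusive) until cumulative growing-degree-days reach the
#' crop's requirement. Seasons not completing within 365 days are censored
#' at 365, flagged, and excluded from the reported means. Reported as the
#' area-weighted mean over land cells per sowing year and, when reference
#' and comparison periods are given, as the change between period means.
#'
#' @param tmean daily mean-temperature [climate_field()].
#' @param params a [crop_params()].
#' @param crop crop name present in `params`.
#' @param regions optional [region_table()] (restricts to land cells).
#' @param reference,comparison optional year vectors for the change rows.
#' @return list with `table` (an [indicator_table()]), `lengths`
#'   ([year, cell] matrix, NA where censored) and `censored_fraction`.
#' @export
crop_season_length <- function(tmean, params, crop, regions = NULL,
                               reference = NULL, comparison = NULL) {
  cp <- params$crops[params$crops$crop == crop, ]
  if (nrow(cp) != 1L) stop(sprintf("unknown crop '%s'", crop))
  m <- field_matrix(tmean)
  gdd <- pmin(pmax(m, cp$t_base), cp$t_cap) - cp$t_base
  ct <- cell_table(tmean$lats, tmean$lons)
  sow <- ifelse(ct$lat >= 0, cp$sowing_doy_nh, cp$sowing_doy_sh)
  yrs <- sort(unique(tmean$years))
  nt <- nrow(m)
  first_serial <- tmean$years[1L] * DAYS_PER_YEAR + tmean$doys[1L]
  lengths <- matrix(NA_real_, length(yrs), ncol(m),
                    dimnames = list(as.character(yrs), NULL))
  censored <- 0L; evaluated <- 0L
  for (yi in seq_along(yrs)) {
    for (cell in seq_len(ncol(m))) {
      start <- yrs[yi] * DAYS_PER_YEAR + sow[cell] - first_serial + 1L
      if (start < 1L || start + 364L > nt) next
      evaluated <- evaluated + 1L
      cs <- cumsum(gdd[start:(start + 364L), cell])
      hit <- which(cs >= cp$gdd_requirement)
      if (length(hit)) lengths[yi, cell] <- hit[1L] else censored <- censored + 1L
    }
  }
  w <- area_weights(tmean$lats, tmean$lons)
  if (!is.null(regions)) w <- w * regions$is_land
  ann <- apply(lengths, 1L, function(x) {
    ok <- !is.na(x) & w > 0
    if (!any(ok)) NA_real_ else sum(w[ok] * x[ok]) / sum(w[ok])
  })
  keep <- !is.na(ann)
  rows <- list(indicator_table(paste0("crop_season_length_", crop), "GLOBAL",
                               names(ann)[keep], ann[keep], "days"))
  if (!is.null(reference) && !is.null(comparison)) {
    mr <- mean(ann[as.character(intersect(yrs, reference))], na.rm = TRUE)
    mc <- mean(ann[as.character(intersect(yrs, comparison))], na.rm = TRUE)
    rows <- c(rows, list(indicator_table(
      paste0("crop_season_length_change_", crop), "GLOBAL",
      paste(period_label(reference), period_label(comparison), sep = " vs "),
      mc - mr, "days")))
  }
  list(table = do.call(bind_indicators, rows), lengths = lengths,
       censored_fraction = if (evaluated > 0) censored / evaluated else NA_real_)
}

#' Coastal sea-surface temperature change
#'
#' Per country, the mean SST over that country's coastal cells in the second
#' period minus the first; globally, the cosine-latitude-weighted change
#' over all coastal cells. Countries without coastal cells are missing.
#'
#' @param sst daily SST [climate_field()].
#' @param regions [region_table()] with coastal flags.
#' @param period1,period2 year vectors.
#' @return an [indicator_table()] of `coastal_sst_change` rows, degC.
#' @export
coastal_sst_anomaly <- function(sst, regions, period1, period2) {
  m <- field_matrix(sst)
  mean_cell <- function(years) colMeans(m[sst$years %in% years, , drop = FALSE])
  delta <- mean_cell(period2) - mean_cell(period1)
  coast <- regions$is_coastal
  if (!any(coast)) stop("no coastal cells flagged in the region table")
  w <- area_weights(sst$lats, sst$lons)
  per <- paste(period_label(period1), period_label(period2), sep = " vs ")
  by_country <- weighted_regional_mean(
    delta[coast], rep(1, sum(coast)), regions$country_code[coast])
  glob <- sum(w[coast] * delta[coast]) / sum(w[coast])
  bind_indicators(
    indicator_table("coastal_sst_change", names(by_country), per, by_country, "degC"),
    indicator_table("coastal_sst_change", "GLOBAL", per, glob, "degC")
  )
}
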