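# Shared fixtures: small fields built in code, the independent run-length
# oracle, and a cached desk-scale synthetic scenario.

# a constant-valued 1-cell-deep field over given years
make_field <- function(values, variable = "tmean", units = "degC",
                       lats = c(0, 10), lons = c(0, 10), years = 2000L) {
  nlat <- length(lats); nlon <- length(lons)
  nt <- length(years) * 365L
  yr <- rep(years, each = 365L)
  doy <- rep(1:365, times = length(years))
  arr <- array(values, dim = c(nt, nlat, nlon))
  climate_field(variable, units, yr, doy, lats, lons, arr)
}

# independent oracle: explicit scan over all maximal runs of TRUE
oracle_runs <- function(cand, min_len) {
  out <- rep(FALSE, length(cand))
  i <- 1L
  while (i <= length(cand)) {
    if (cand[i]) {
      j <- i
      while (j < length(cand) && cand[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len) out[i:j] <- TRUE
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# run a candidate pattern through the full detect_heatwaves path on a
# 1-cell grid: baseline year is constant 20 (thresholds 20), pattern days
# are 25 (candidate) or 15 (not)
hw_days_from_pattern <- function(pattern, min_duration = 2L) {
  n <- length(pattern)
  vals <- c(rep(20, 365), ifelse(pattern, 25, 15), rep(15, 365 - n))
  f <- make_field(vals, lats = 0, lons = 0, years = c(2000L, 2001L))
  fmin <- climate_field("tmin", "degC", f$years, f$doys, f$lats, f$lons, f$values)
  fmax <- climate_field("tmax", "degC", f$years, f$doys, f$lats, f$lons, f$values)
  cl <- build_percentile_climatology(fmin, c(2000L, 2000L), 0.95, 1L)
  clx <- build_percentile_climatology(fmax, c(2000L, 2000L), 0.95, 1L)
  hp <- heatwave_params(0.95, c(2000L, 2000L), min_duration)
  hw <- detect_heatwaves(fmin, fmax, cl, clx, hp)
  as.logical(hw$values[365L + seq_len(n), 1, 1])
}

# small cached scenario + derived products shared across test files
.fix_env <- new.env()
small_scenario <- function() {
  if (is.null(.fix_env$sc)) {
    .fix_env$sc <- climate_scenario(n_lat = 6L, n_lon = 8L, years = 1986:2015,
                                    seed = 1234L)
    .fix_env$fields <- gen_climate_fields(.fix_env$sc)
    .fix_env$pr <- gen_population_and_regions(.fix_env$sc, n_countries = 4L)
  }
  list(sc = .fix_env$sc, fields = .fix_env$fields,
       pop = .fix_env$pr$pop, regions = .fix_env$pr$regions)
}

make_monthly <- function(values_by_month, lats = c(0, 40), lons = c(0, 10),
                         years = 2000L, variable = "tmean", units = "degC") {
  ny <- length(years)
  nlat <- length(lats); nlon <- length(lons)
  arr <- array(rep(values_by_month, times = ny * nlat * nlon),
               dim = c(12L * ny, nlat, nlon))
  structure(list(variable = variable, units = units,
                 years = rep(years, each = 12L), months = rep(1:12, ny),
                 lats = lats, lons = lons, values = arr),
            class = "monthly_field")
}
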