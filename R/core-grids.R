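# Percentile climatologies, weighted aggregation, and the tidy indicator,
# population and region containers shared by every indicator stage.

# Column-wise type-7 empirical quantile (linear interpolation between order
# statistics) of a [n, ncell] matrix; NA-free fast path via full column sort.
col_quantile7 <- function(m, p) {
  n <- nrow(m)
  if (n == 0L) stop("empty sample for quantile")
  if (anyNA(m)) {
    return(apply(m, 2L, function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) NA_real_ else unname(stats::quantile(x, probs = p, type = 7))
    }))
  }
  s <- apply(m, 2L, sort.int, method = "quick")
  if (is.null(dim(s))) s <- matrix(s, nrow = n)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  g <- h - lo
  qs <- s[lo, ]
  if (g > 0) {
    upd <- s[hi, ] != qs          # same guard and arithmetic as stats::quantile
    qs[upd] <- (1 - g) * qs[upd] + g * s[hi, ][upd]
  }
  qs
}

#' Build a per-calendar-day percentile climatology
#'
#' For every grid cell and calendar day (1..365), pools all baseline-period
#' values whose calendar day falls within a centred window of
#' `window_days` days (circular across the year boundary) and takes the
#' empirical percentile with the linear-interpolation ("type 7") definition.
#' With the default `window_days = 1` the pool is all baseline values of that
#' exact calendar day across years.
#'
#' @param field a daily [climate_field()].
#' @param baseline length-2 integer vector, first and last baseline year
#'   (default `c(1986, 2005)`); must lie inside the field's time span.
#' @param percentile fraction in (0, 1), default 0.95.
#' @param window_days odd window width in days, default 1.
#' @return an object of class `percentile_climatology` with a
#'   `thresholds` array of dim c(365, n_lat, n_lon).
#' @export
build_percentile_climatology <- function(field, baseline = c(1986L, 2005L),
                                         percentile = 0.95, window_days = 1L) {
  stopifnot(length(baseline) == 2L)
  baseline <- as.integer(baseline)
  if (percentile <= 0 || percentile > 1) stop("percentile must lie in (0, 1]")
  window_days <- as.integer(window_days)
  if (window_days < 1L || window_days %% 2L == 0L) stop("window_days must be odd and >= 1")
  if (window_days > DAYS_PER_YEAR) stop("window larger than year length")
  yr <- range(field$years)
  if (baseline[1L] < yr[1L] || baseline[2L] > yr[2L] || baseline[1L] > baseline[2L])
    stop("baseline period outside the data span")

  half <- (window_days - 1L) %/% 2L
  in_base <- field$years >= baseline[1L] & field$years <= baseline[2L]
  m <- field_matrix(field)
  nlat <- length(field$lats); nlon <- length(field$lons)
  thr <- array(NA_real_, dim = c(DAYS_PER_YEAR, nlat, nlon))
  # index baseline rows by calendar day once
  rows_by_doy <- split(which(in_base), field$doys[in_base])
  for (d in seq_len(DAYS_PER_YEAR)) {
    wdoys <- ((d - half - 1L + seq_len(window_days) - 1L) %% DAYS_PER_YEAR) + 1L
    rows <- unlist(rows_by_doy[as.character(wdoys)], use.names = FALSE)
    if (is.null(rows) || !length(rows)) next
    thr[d, , ] <- col_quantile7(m[rows, , drop = FALSE], percentile)
  }
  structure(
    list(variable = field$variable, baseline = baseline, percentile = percentile,
         window_days = window_days, lats = field$lats, lons = field$lons,
         thresholds = thr),
    class = "percentile_climatology"
  )
}

# thresholds as [time, cell] matrix aligned with a field's time axis
threshold_matrix <- function(clim, field) {
  nlat <- length(clim$lats); nlon <- length(clim$lons)
  tm <- clim$thresholds
  dim(tm) <- c(DAYS_PER_YEAR, nlat * nlon)
  tm[field$doys, , drop = FALSE]
}

#' Weighted regional mean of per-cell values
#'
#' Computes, for each region, the weighted mean of `x` over that region's
#' cells. NA values are excluded from numerator and denominator alike; a
#' region whose total usable weight is zero is reported as NA (missing),
#' never as zero.
#'
#' @param x numeric vector of per-cell values.
#' @param weights non-negative numeric vector, same length as `x` (e.g.
#'   [area_weights()] or population counts).
#' @param regions factor or character vector assigning each cell to a
#'   region; NA cells are dropped.
#' @return named numeric vector, one value per region level.
#' @export
weighted_regional_mean <- function(x, weights, regions) {
  if (length(x) != length(weights) || length(x) != length(regions))
    stop("grid mismatch: x, weights and regions must have equal length")
  if (any(weights < 0, na.rm = TRUE)) stop("negative weights are not allowed")
  f <- factor(regions)
  ok <- !is.na(x) & !is.na(weights) & !is.na(f)
  num <- tapply(x[ok] * weights[ok], f[ok], sum)
  den <- tapply(weights[ok], f[ok], sum)
  out <- rep(NA_real_, nlevels(f))
  names(out) <- levels(f)
  idx <- names(num)[!is.na(den) & den > 0]
  out[idx] <- num[idx] / den[idx]
  out
}

#' Construct a validated indicator table
#'
#' The tidy long-format output shared by every indicator:
#' one row per (indicator_id, region, period), with a value and its units.
#'
#' @param indicator_id,region,period,value,units column vectors (recycled to
#'   a common length). `region` is a country code, an HDI group or "GLOBAL";
#'   `period` a year or "YYYY-YYYY" range.
#' @return data.frame of class `indicator_table`, sorted by
#'   (indicator_id, region, period).
#' @export
indicator_table <- function(indicator_id = character(), region = character(),
                            period = character(), value = numeric(),
                            units = character()) {
  if (length(value) == 0L) {
    indicator_id <- region <- period <- units <- character()
  }
  df <- data.frame(indicator_id = as.character(indicator_id),
                   region = as.character(region),
                   period = as.character(period),
                   value = as.numeric(value),
                   units = as.character(units),
                   stringsAsFactors = FALSE)
  if (any(!nzchar(df$units))) stop("units must be non-empty")
  key <- paste(df$indicator_id, df$region, df$period, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (indicator_id, region, period) keys")
  df <- df[order(df$indicator_id, df$region, df$period), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("indicator_table", "data.frame")
  df
}

#' Row-bind indicator tables
#'
#' @param ... `indicator_table` objects.
#' @return a single validated `indicator_table`.
#' @export
bind_indicators <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, function(p) !is.null(p) && nrow(p) > 0, logical(1))]
  if (!length(parts)) return(indicator_table())
  df <- do.call(rbind, lapply(parts, as.data.frame))
  indicator_table(df$indicator_id, df$region, df$period, df$value, df$units)
}

#' Write an indicator table to CSV
#'
#' Writes `indicator_id,region,period,value,units` with a stable row order
#' so identical tables produce byte-identical files; refuses duplicate keys.
#'
#' @param table an [indicator_table()].
#' @param path output CSV path.
#' @export
write_indicator_table <- function(table, path) {
  table <- indicator_table(table$indicator_id, table$region, table$period,
                           table$value, table$units)
  df <- as.data.frame(table)
  df$value <- sprintf("%.10g", df$value)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an indicator table written by [write_indicator_table()]
#'
#' @param path CSV path.
#' @return an `indicator_table`.
#' @export
read_indicator_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(indicator_id = "character",
                                       region = "character",
                                       period = "character",
                                       value = "numeric",
                                       units = "character"))
  indicator_table(df$indicator_id, df$region, df$period, df$value, df$units)
}

#' Construct a population grid
#'
#' Per-cell population counts stratified by age group (or, for the labour
#' module, by employment sector), on the same grid as the climate fields it
#' is combined with.
#'
#' @param lats,lons ascending coordinate vectors.
#' @param age_groups character labels, e.g. `c("under1", "1to64", "65plus")`.
#' @param counts non-negative array with dim c(n_groups, n_lat, n_lon).
#' @return object of class `population_grid`.
#' @export
population_grid <- function(lats, lons, age_groups, counts) {
  if (!identical(dim(counts), c(length(age_groups), length(lats), length(lons))))
    stop("counts must have dim c(n_groups, n_lat, n_lon)")
  if (any(counts < 0, na.rm = TRUE)) stop("population counts must be non-negative")
  structure(list(lats = as.numeric(lats), lons = as.numeric(lons),
                 age_groups = as.character(age_groups), counts = counts),
            class = "population_grid")
}

#' Per-cell counts for one age group, in cell order
#'
#' @param pop a [population_grid()].
#' @param group age-group label present in `pop$age_groups`.
#' @return numeric vector, one count per cell (lat fastest).
#' @export
population_vector <- function(pop, group) {
  i <- match(group, pop$age_groups)
  if (is.na(i)) stop(sprintf("age group '%s' not present in population grid", group))
  as.vector(pop$counts[i, , ])
}

#' Validate a region table
#'
#' A region table carries the static per-cell attributes: country code, HDI
#' group, elevation, land/coast flags, land class, optional urban-centre id
#' and annual NDVI. Rows must be in canonical cell order (lat fastest).
#'
#' @param df data.frame with columns cell, lat_idx, lon_idx, lat, lon,
#'   country_code, hdi_group, elevation_m, is_land, is_coastal, land_class,
#'   urban_centre_id, ndvi.
#' @return the validated data.frame with class `region_table`.
#' @export
region_table <- function(df) {
  need <- c("cell", "lat_idx", "lon_idx", "lat", "lon", "country_code",
            "hdi_group", "elevation_m", "is_land", "is_coastal",
            "land_class", "urban_centre_id", "ndvi")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("region table missing columns: ", paste(miss, collapse = ", "))
  if (!identical(df$cell, seq_len(nrow(df)))) stop("region table rows must be in cell order")
  if (any(df$is_land & is.na(df$country_code)))
    stop("every land cell must map to exactly one country_code")
  if (any(!is.na(df$ndvi) & (df$ndvi < -1 | df$ndvi > 1)))
    stop("ndvi must lie within [-1, 1]")
  bad_hdi <- !is.na(df$hdi_group) &
    !df$hdi_group %in% c("low", "medium", "high", "very_high")
  if (any(bad_hdi)) stop("hdi_group must be low/medium/high/very_high")
  class(df) <- c("region_table", "data.frame")
  df
}
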