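# Gridded daily climate fields on a regular lat-lon grid.
#
# Internal layout: values is a 3-d array [time, lat, lon]; a "cell" index
# enumerates grid cells with latitude varying fastest, so that
# matrix(values, nrow = ntime) has one column per cell in cell order.

DAYS_PER_YEAR <- 365L
NOLEAP_MONTH_LENGTHS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
NOLEAP_MONTH_STARTS <- cumsum(c(1L, NOLEAP_MONTH_LENGTHS[-12L]))

.known_units <- c(
  tmean = "degC", tmin = "degC", tmax = "degC", precip = "mm",
  rh = "%", sst = "degC", sss = "psu"
)

#' Month of a no-leap calendar day
#'
#' @param doy integer day of year in 1..365 (365-day no-leap calendar).
#' @return integer month in 1..12.
#' @export
doy_to_month <- function(doy) {
  findInterval(doy, NOLEAP_MONTH_STARTS)
}

#' Construct a daily gridded climate field
#'
#' A `climate_field` holds one physical variable on a regular latitude by
#' longitude grid with a strictly daily time axis. Two calendars are
#' supported: the 365-day no-leap calendar used by the synthetic generator,
#' and the proleptic Gregorian calendar for loaded data (29 February is
#' mapped to calendar day 59 so climatology lookups always index 1..365).
#'
#' @param variable variable name, e.g. "tmean", "precip", "rh", "sst", "sss".
#' @param units unit string; checked against the expected unit when the
#'   variable is one the package knows ("degC", "mm", "%", "psu").
#' @param years,doys integer vectors (one element per day) giving the year
#'   and the 1..365 calendar day of each time step.
#' @param lats,lons cell-centre coordinates in degrees, strictly ascending;
#'   latitudes in [-90, 90], longitudes in [-180, 180).
#' @param values numeric array with dim c(length(years), length(lats),
#'   length(lons)); NA marks missing cells.
#' @param calendar "noleap" or "gregorian".
#' @param dates optional Date vector (required for "gregorian"), used for the
#'   daily-step check when leap days make (year, doy) non-unique.
#' @return an object of class `climate_field`.
#' @export
climate_field <- function(variable, units, years, doys, lats, lons, values,
                          calendar = c("noleap", "gregorian"), dates = NULL) {
  calendar <- match.arg(calendar)
  years <- as.integer(years)
  doys <- as.integer(doys)
  if (!is.character(variable) || length(variable) != 1L || !nzchar(variable))
    stop("variable name must be a non-empty string")
  if (!is.character(units) || length(units) != 1L || !nzchar(units))
    stop("units must be declared (non-empty string)")
  if (variable %in% names(.known_units) && units != .known_units[[variable]])
    stop(sprintf("units '%s' inconsistent with variable '%s' (expected '%s')",
                 units, variable, .known_units[[variable]]))
  if (any(diff(lats) <= 0) || any(lats < -90) || any(lats > 90))
    stop("lats must be strictly ascending within [-90, 90]")
  if (any(diff(lons) <= 0) || any(lons < -180) || any(lons >= 180))
    stop("lons must be strictly ascending within [-180, 180)")
  nt <- length(years)
  if (length(doys) != nt) stop("years and doys must have equal length")
  if (any(doys < 1L | doys > DAYS_PER_YEAR)) stop("doys must lie in 1..365")
  if (!identical(dim(values), c(nt, length(lats), length(lons))))
    stop("values must be an array with dim c(n_time, n_lat, n_lon)")
  if (calendar == "noleap") {
    serial <- years * DAYS_PER_YEAR + doys
    if (nt > 1L && any(diff(serial) != 1L))
      stop("non-daily time step: time axis must advance by exactly one day")
  } else {
    if (is.null(dates)) stop("gregorian calendar requires a dates vector")
    if (length(dates) != nt) stop("dates length must match time axis")
    if (nt > 1L && any(diff(as.integer(dates)) != 1L))
      stop("non-daily time step: time axis must advance by exactly one day")
  }
  structure(
    list(variable = variable, units = units, years = years, doys = doys,
         lats = as.numeric(lats), lons = as.numeric(lons),
         values = values, calendar = calendar, dates = dates),
    class = "climate_field"
  )
}

#' @export
print.climate_field <- function(x, ...) {
  cat(sprintf("<climate_field> %s [%s], %d days (%d-%d), %d x %d grid (%s)\n",
              x$variable, x$units, length(x$years), min(x$years), max(x$years),
              length(x$lats), length(x$lons), x$calendar))
  invisible(x)
}

n_cells <- function(field) length(field$lats) * length(field$lons)

# [time, cell] matrix view, cells in lat-fastest order
field_matrix <- function(field) {
  m <- field$values
  dim(m) <- c(length(field$years), n_cells(field))
  m
}

#' Per-cell grid table for a field's grid
#'
#' Enumerates grid cells in the package's canonical order (latitude varying
#' fastest) with their coordinates and indices.
#'
#' @param lats,lons ascending coordinate vectors.
#' @return data.frame with columns cell, lat_idx, lon_idx, lat, lon.
#' @export
cell_table <- function(lats, lons) {
  g <- expand.grid(lat_idx = seq_along(lats), lon_idx = seq_along(lons))
  data.frame(cell = seq_len(nrow(g)), lat_idx = g$lat_idx, lon_idx = g$lon_idx,
             lat = lats[g$lat_idx], lon = lons[g$lon_idx])
}

#' Cosine-latitude area weights in cell order
#'
#' Relative cell areas on a regular lat-lon grid are proportional to the
#' cosine of the cell-centre latitude.
#'
#' @param lats,lons ascending coordinate vectors.
#' @return numeric vector, one weight per cell (lat fastest).
#' @export
area_weights <- function(lats, lons) {
  rep(cos(lats * pi / 180), times = length(lons))
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$lats, b$lats)) && isTRUE(all.equal(a$lons, b$lons))
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("grid mismatch: objects are not on the same lat/lon grid")
  invisible(TRUE)
}

noleap_doy_from_date <- function(dates) {
  mo <- as.integer(format(dates, "%m"))
  dy <- as.integer(format(dates, "%d"))
  dy <- ifelse(mo == 2L & dy == 29L, 28L, dy)  # Feb 29 -> calendar day 59
  NOLEAP_MONTH_STARTS[mo] + dy - 1L
}

#' Write a climate field to the package's long-format CSV dialect
#'
#' The file starts with `# variable:`, `# units:` and `# calendar:` metadata
#' lines followed by a `date,lat,lon,value` table. No-leap dates are written
#' as `YYYY-DDD` (day of year); Gregorian dates as ISO `YYYY-MM-DD`. The
#' format round-trips losslessly through [load_climate_field()].
#'
#' @param field a `climate_field`.
#' @param path output file path.
#' @export
write_climate_field <- function(field, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# variable: ", field$variable),
               paste0("# units: ", field$units),
               paste0("# calendar: ", field$calendar)), con)
  ct <- cell_table(field$lats, field$lons)
  date_str <- if (field$calendar == "noleap") {
    sprintf("%04d-%03d", field$years, field$doys)
  } else {
    format(field$dates, "%Y-%m-%d")
  }
  m <- field_matrix(field)
  df <- data.frame(
    date = rep(date_str, times = nrow(ct)),
    lat = rep(ct$lat, each = length(field$years)),
    lon = rep(ct$lon, each = length(field$years)),
    value = as.vector(m)
  )
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a climate field from the package's CSV dialect
#'
#' Validates all `climate_field` invariants on load: units must be declared
#' in the metadata header, the time axis must be strictly daily, latitudes
#' are sorted ascending (values re-ordered accordingly) and longitudes given
#' in [0, 360) are rewrapped to [-180, 180) with values permuted to match.
#'
#' @param path file written by [write_climate_field()] or following the same
#'   `date,lat,lon,value` long format with metadata header lines.
#' @param variable optional; when given, checked against the file metadata.
#' @return a validated `climate_field`.
#' @export
load_climate_field <- function(path, variable = NULL) {
  header <- character()
  con <- file(path, "r")
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || !startsWith(line, "#")) break
    header <- c(header, line)
  }
  close(con)
  meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), header, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1L]))
  }
  var <- meta("variable"); units <- meta("units"); calendar <- meta("calendar")
  if (is.na(units) || !nzchar(units)) stop("load error: undeclared units in file header")
  if (is.na(var)) stop("load error: undeclared variable in file header")
  if (is.na(calendar)) calendar <- "gregorian"
  if (!is.null(variable) && variable != var)
    stop(sprintf("load error: file holds variable '%s', not '%s'", var, variable))

  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("date", "lat", "lon", "value")
  if (!all(need %in% names(df)))
    stop("load error: missing coordinate variables (need date, lat, lon, value)")

  if (calendar == "noleap") {
    parts <- strsplit(as.character(df$date), "-", fixed = TRUE)
    years <- vapply(parts, function(p) as.integer(p[1L]), integer(1))
    doys <- vapply(parts, function(p) as.integer(p[2L]), integer(1))
    tkey <- years * DAYS_PER_YEAR + doys
    dates <- NULL
  } else {
    dates_all <- as.Date(df$date)
    if (anyNA(dates_all)) stop("load error: unparseable dates")
    tkey <- as.integer(dates_all)
  }
  ut <- sort(unique(tkey))
  lats_raw <- sort(unique(df$lat))
  lons_raw <- unique(df$lon)
  # rewrap longitudes from [0, 360) to [-180, 180)
  lon_wrapped <- ifelse(lons_raw >= 180, lons_raw - 360, lons_raw)
  lons <- sort(lon_wrapped)

  ti <- match(tkey, ut)
  li <- match(df$lat, lats_raw)
  xi <- match(ifelse(df$lon >= 180, df$lon - 360, df$lon), lons)
  arr <- array(NA_real_, dim = c(length(ut), length(lats_raw), length(lons)))
  arr[cbind(ti, li, xi)] <- df$value

  if (calendar == "noleap") {
    years <- ut %/% DAYS_PER_YEAR
    doys <- ut %% DAYS_PER_YEAR
    years[doys == 0L] <- years[doys == 0L] - 1L
    doys[doys == 0L] <- DAYS_PER_YEAR
  } else {
    dates <- as.Date(ut, origin = "1970-01-01")
    years <- as.integer(format(dates, "%Y"))
    doys <- noleap_doy_from_date(dates)
  }
  climate_field(var, units, years, doys, lats_raw, lons, arr,
                calendar = calendar, dates = if (calendar == "noleap") NULL else dates)
}

#' Subset a climate field by years
#'
#' @param field a `climate_field`.
#' @param years integer vector of years to keep.
#' @return a `climate_field` restricted to those years.
#' @export
subset_years <- function(field, years) {
  keep <- field$years %in% years
  if (!any(keep)) stop("no time steps inside the requested years")
  climate_field(field$variable, field$units, field$years[keep], field$doys[keep],
                field$lats, field$lons,
                field$values[keep, , , drop = FALSE],
                calendar = field$calendar,
                dates = if (is.null(field$dates)) NULL else field$dates[keep])
}
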