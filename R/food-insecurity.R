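# Heatwave days in crop growing seasons, the country-by-year fixed-effects
# regression of food-insecurity prevalence on heatwave-day anomalies, and
# the attribution of prevalence change to people affected.

#' Growing-season heatwave-day anomalies per country-year
#'
#' Counts heatwave days falling inside any crop-calendar window of the year,
#' area-weighted over each country's cropland cells (all land cells when a
#' country has no cropland class), and subtracts the country's baseline
#' annual mean.
#'
#' @param hw_days 0/1 field from [detect_heatwaves()].
#' @param regions a [region_table()].
#' @param crop_windows list of length-2 integer vectors (doy ranges, may be
#'   given per hemisphere via `nh`/`sh` names); default: May-September in
#'   the north, November-March (wrapping) in the south.
#' @param baseline year vector for the anomaly reference.
#' @return data.frame (country, year, hw_days, hw_anomaly).
#' @export
growing_season_heatwave_days <- function(hw_days, regions,
                                         crop_windows = NULL,
                                         baseline = 1986:2005) {
  if (is.null(crop_windows))
    crop_windows <- list(nh = list(c(121L, 273L)), sh = list(c(305L, 90L)))
  in_windows <- function(doys, windows) {
    hit <- rep(FALSE, length(doys))
    for (wnd in windows) {
      if (length(wnd) != 2L || any(is.na(wnd))) stop("empty crop window")
      hit <- hit | if (wnd[1L] <= wnd[2L]) {
        doys >= wnd[1L] & doys <= wnd[2L]
      } else {
        doys >= wnd[1L] | doys <= wnd[2L]  # wraps the year boundary
      }
    }
    if (!any(hit)) stop("empty crop window")
    hit
  }
  m <- field_matrix(hw_days)
  ct <- cell_table(hw_days$lats, hw_days$lons)
  nh_hit <- in_windows(hw_days$doys, crop_windows$nh)
  sh_hit <- in_windows(hw_days$doys, crop_windows$sh)
  hit <- outer(nh_hit, ct$lat >= 0) | outer(sh_hit, ct$lat < 0)
  cnt <- rowsum(m * hit, hw_days$years)  # windowed hw days per cell-year
  yrs <- as.integer(rownames(cnt))
  w_area <- area_weights(hw_days$lats, hw_days$lons)
  countries <- sort(unique(stats::na.omit(regions$country_code)))
  out <- list()
  for (co in countries) {
    cells <- which(!is.na(regions$country_code) & regions$country_code == co)
    crop <- cells[!is.na(regions$land_class[cells]) &
                    regions$land_class[cells] == "cropland"]
    if (!length(crop)) crop <- cells
    w <- w_area[crop]
    days <- as.vector(cnt[, crop, drop = FALSE] %*% w) / sum(w)
    base_mean <- mean(days[yrs %in% baseline])
    out[[co]] <- data.frame(country = co, year = yrs, hw_days = days,
                            hw_anomaly = days - base_mean,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Specification of the food-insecurity panel regression
#'
#' @param effect_mode "constant_beta" for a single exposure coefficient, or
#'   "per_year_beta" for year-specific coefficients (the time-varying
#'   variant).
#' @param include_country_effects,include_year_effects fixed-effect switches
#'   (both default TRUE).
#' @param se_mode "cluster_by_country" (default) or "classical".
#' @return object of class `regression_spec`.
#' @export
regression_spec <- function(effect_mode = c("constant_beta", "per_year_beta"),
                            include_country_effects = TRUE,
                            include_year_effects = TRUE,
                            se_mode = c("cluster_by_country", "classical")) {
  structure(list(effect_mode = match.arg(effect_mode),
                 include_country_effects = include_country_effects,
                 include_year_effects = include_year_effects,
                 se_mode = match.arg(se_mode)),
            class = "regression_spec")
}

# two-way within transformation on a balanced panel:
# x - mean_country - mean_year + overall mean (single pass is exact when
# the panel is balanced; iterated to convergence otherwise)
within_transform <- function(x, country, year) {
  for (it in 1:50) {
    x <- x - stats::ave(x, country, FUN = mean)
    x <- x - stats::ave(x, year, FUN = mean)
    if (max(abs(tapply(x, country, mean))) < 1e-12 &&
        max(abs(tapply(x, year, mean))) < 1e-12) break
  }
  x
}

#' Fit the food-insecurity fixed-effects regression
#'
#' Least squares on `prevalence ~ country effects + year effects + beta *
#' hw_anomaly`, estimated by the within transformation (demeaning by country
#' and by year), which on a balanced panel equals the full dummy-variable
#' solution. In `per_year_beta` mode the exposure is interacted with year
#' indicators. Standard errors are classical or clustered by country.
#'
#' @param panel data.frame with columns country, year, prevalence
#'   (proportion in [0, 1]).
#' @param exposure data.frame with columns country, year, hw_anomaly.
#' @param spec a [regression_spec()].
#' @return object of class `fies_fit`: beta_hat in percentage points of
#'   prevalence per heatwave-day (named per year in per-year mode), se,
#'   residual variance, n_obs, and the data used.
#' @export
fit_fies_regression <- function(panel, exposure, spec = regression_spec()) {
  d <- merge(panel[, c("country", "year", "prevalence")],
             exposure[, c("country", "year", "hw_anomaly")],
             by = c("country", "year"))
  if (length(unique(d$country)) < 2L || length(unique(d$year)) < 2L)
    stop("panel needs at least 2 countries and 2 years")
  d <- d[order(d$country, d$year), ]
  d$prevalence_pp <- 100 * d$prevalence  # coefficients in percentage points
  co <- factor(d$country); yrf <- factor(d$year)

  X <- if (spec$effect_mode == "constant_beta") {
    matrix(d$hw_anomaly, ncol = 1L, dimnames = list(NULL, "beta"))
  } else {
    stats::model.matrix(~ 0 + yrf:hw_anomaly, data = data.frame(yrf, hw_anomaly = d$hw_anomaly))
  }
  y <- d$prevalence_pp
  if (spec$include_country_effects && spec$include_year_effects) {
    yt <- within_transform(y, co, yrf)
    Xt <- apply(X, 2L, within_transform, country = co, year = yrf)
  } else if (spec$include_country_effects) {
    yt <- y - stats::ave(y, co, FUN = mean)
    Xt <- apply(X, 2L, function(x) x - stats::ave(x, co, FUN = mean))
  } else if (spec$include_year_effects) {
    yt <- y - stats::ave(y, yrf, FUN = mean)
    Xt <- apply(X, 2L, function(x) x - stats::ave(x, yrf, FUN = mean))
  } else {
    yt <- y - mean(y); Xt <- apply(X, 2L, function(x) x - mean(x))
  }
  Xt <- as.matrix(Xt)
  qr_x <- qr(Xt)
  if (qr_x$rank < ncol(Xt)) {
    drop_cols <- colnames(Xt)[qr_x$pivot[(qr_x$rank + 1L):ncol(Xt)]]
    stop("rank-deficient design after the within transformation; collinear terms: ",
         paste(drop_cols, collapse = ", "))
  }
  beta <- qr.coef(qr_x, yt)
  resid <- yt - Xt %*% beta
  n <- length(y)
  df_fe <- (spec$include_country_effects) * (nlevels(co) - 1L) +
    (spec$include_year_effects) * (nlevels(yrf) - 1L) + 1L
  dof <- n - df_fe - ncol(Xt)
  sigma2 <- sum(resid^2) / max(dof, 1L)
  XtXinv <- chol2inv(qr.R(qr_x))
  if (spec$se_mode == "classical") {
    vcov <- sigma2 * XtXinv
  } else {
    meat <- matrix(0, ncol(Xt), ncol(Xt))
    for (g in levels(co)) {
      idx <- which(co == g)
      sg <- crossprod(Xt[idx, , drop = FALSE], resid[idx])
      meat <- meat + sg %*% t(sg)
    }
    G <- nlevels(co)
    adj <- G / (G - 1) * (n - 1) / max(n - df_fe - ncol(Xt), 1L)
    vcov <- adj * XtXinv %*% meat %*% XtXinv
  }
  se <- sqrt(diag(vcov))
  names(beta) <- names(se) <-
    if (spec$effect_mode == "constant_beta") "beta" else
      sub("^yrf(\\d+):hw_anomaly$", "\\1", colnames(X))
  structure(list(beta_hat = beta, se = se, sigma2 = sigma2, n_obs = n,
                 spec = spec, vcov = vcov,
                 data = d),
            class = "fies_fit")
}

#' @export
print.fies_fit <- function(x, ...) {
  cat("<fies_fit>", x$n_obs, "observations;", x$spec$effect_mode, "\n")
  print(data.frame(beta = x$beta_hat, se = x$se))
  invisible(x)
}

#' Attribute food-insecurity prevalence change to heatwave days
#'
#' Per country, the percentage-point prevalence change in the target year is
#' `beta_hat(year) * hw_anomaly`; people-equivalents multiply by the
#' country's population. Globally: population-weighted mean change and the
#' sum of people-equivalents.
#'
#' @param fit a `fies_fit`.
#' @param exposure data.frame (country, year, hw_anomaly).
#' @param panel data.frame with country, year, population.
#' @param year target year.
#' @return an [indicator_table()] with per-country and GLOBAL rows.
#' @export
attribute_food_insecurity <- function(fit, exposure, panel, year) {
  b <- if (length(fit$beta_hat) == 1L) fit$beta_hat else {
    if (!as.character(year) %in% names(fit$beta_hat))
      stop("no per-year coefficient for the target year")
    fit$beta_hat[[as.character(year)]]
  }
  ex <- exposure[exposure$year == year, ]
  pp <- panel[panel$year == year, c("country", "population")]
  d <- merge(ex, pp, by = "country")
  d$dprev_pp <- unname(b) * d$hw_anomaly          # percentage points
  d$people <- d$dprev_pp / 100 * d$population
  glob_pp <- sum(d$dprev_pp * d$population) / sum(d$population)
  bind_indicators(
    indicator_table("fies_prevalence_change", d$country, as.character(year),
                    d$dprev_pp, "percentage points"),
    indicator_table("fies_prevalence_change", "GLOBAL", as.character(year),
                    glob_pp, "percentage points"),
    indicator_table("fies_people_affected", d$country, as.character(year),
                    d$people, "persons"),
    indicator_table("fies_people_affected", "GLOBAL", as.character(year),
                    sum(d$people), "persons")
  )
}
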