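test_that("run-length rule keeps exactly the qualifying runs", {
  cand <- rep(FALSE, 12)
  cand[c(3, 4, 5, 9)] <- TRUE
  expect_identical(which(flag_min_runs(cand, 2L)), c(3L, 4L, 5L))
  # an isolated candidate day is never a heatwave day
  expect_false(any(flag_min_runs(c(rep(FALSE, 5), TRUE, rep(FALSE, 5)), 2L)))
  expect_identical(flag_min_runs(logical(0), 2L), logical(0))
})

test_that("heatwave detection matches the run-enumeration oracle end to end", {
  patterns <- list(
    c(rep(FALSE, 2), TRUE, TRUE, TRUE, rep(FALSE, 3), TRUE, FALSE),
    rep(TRUE, 7),
    rep(FALSE, 7)
  )
  set.seed(21)
  for (len in c(20, 50)) patterns <- c(patterns, list(runif(len) < 0.4))
  for (p in patterns) {
    expect_identical(hw_days_from_pattern(p, 2L), oracle_runs(p, 2L))
    expect_identical(hw_days_from_pattern(p, 3L), oracle_runs(p, 3L))
  }
})

test_that("heatwave detection demands matched climatology parameters", {
  f <- make_field(20, years = 2000:2001)
  cl_ok <- build_percentile_climatology(f, c(2000L, 2000L), 0.95)
  cl_bad <- build_percentile_climatology(f, c(2000L, 2001L), 0.95)
  hp <- heatwave_params(0.95, c(2000L, 2000L))
  expect_error(detect_heatwaves(f, f, cl_ok, cl_bad, hp), "baseline")
})

test_that("summer exposure anomaly reproduces hand-weighted means", {
  # uniform +1 shift: both weightings give exactly 1
  nlat <- 2L; nlon <- 2L
  years <- 2000:2003
  nt <- length(years) * 365L
  vals <- array(10, dim = c(nt, nlat, nlon))
  shift <- rep(years, each = 365L) >= 2002L
  vals <- vals + array(shift, dim = dim(vals))
  f <- climate_field("tmean", "degC", rep(years, each = 365L),
                     rep(1:365, length(years)), c(10, 20), c(0, 10), vals)
  counts <- array(1, dim = c(1L, nlat, nlon))
  pop <- population_grid(c(10, 20), c(0, 10), "all", counts)
  tab <- summer_exposure_anomaly(f, pop, NULL, 2000:2001, 2002:2003)
  expect_equal(tab$value, rep(1, nrow(tab)))

  # two equal-area cells, anomalies 0.2 and 0.6, population 1:9
  lat <- c(5, 5)
  v2 <- array(10, dim = c(nt, 1L, 2L))
  v2[shift, 1, 1] <- 10.2
  v2[shift, 1, 2] <- 10.6
  f2 <- climate_field("tmean", "degC", rep(years, each = 365L),
                      rep(1:365, length(years)), 5, c(0, 10), v2)
  pop2 <- population_grid(5, c(0, 10), "all", array(c(1, 9), dim = c(1, 1, 2)))
  t2 <- summer_exposure_anomaly(f2, pop2, NULL, 2000:2001, 2002:2003)
  t2d <- as.data.frame(t2)
  expect_equal(t2d$value[t2d$indicator_id == "summer_exposure_anomaly_areaweighted"], 0.4)
  expect_equal(t2d$value[t2d$indicator_id == "summer_exposure_anomaly_popweighted"], 0.56)
})

test_that("heatwave person-days follow the hand sums", {
  years <- 2000:2001
  hwv <- array(0, dim = c(730L, 1L, 2L))
  hwv[366:367, 1, 1] <- 1              # 2 hw days in cell 1, year 2001
  hwv[366:369, 1, 2] <- 1              # 4 hw days in cell 2, year 2001
  hw <- climate_field("heatwave_day", "dimensionless", rep(years, each = 365L),
                      rep(1:365, 2L), 5, c(0, 10), hwv)
  pop <- population_grid(5, c(0, 10), "adult", array(c(100, 300), c(1, 1, 2)))
  tab <- as.data.frame(heatwave_exposure(hw, pop, "adult",
                                         baseline = 2000L, target = 2001L))
  pd <- tab$value[tab$indicator_id == "heatwave_person_days_adult"]
  expect_equal(pd, 100 * 2 + 300 * 4)            # 1400 person-days
  dpp <- tab$value[tab$indicator_id == "heatwave_days_per_person_adult"]
  expect_equal(dpp, 1400 / 400)                  # 3.5 days per person
  anom <- tab$value[tab$indicator_id == "heatwave_person_days_anomaly_adult"]
  expect_equal(anom, 1400)                       # baseline year has none
  expect_error(heatwave_exposure(hw, pop, "child", 2000L, 2001L), "age group")
})

test_that("person-days are additive over age groups and cells", {
  s <- small_scenario()
  cl_min <- build_percentile_climatology(s$fields$tmin, c(1986L, 2005L))
  cl_max <- build_percentile_climatology(s$fields$tmax, c(1986L, 2005L))
  hw <- detect_heatwaves(s$fields$tmin, s$fields$tmax, cl_min, cl_max,
                         heatwave_params())
  total_by_group <- vapply(s$pop$age_groups, function(g) {
    t <- as.data.frame(heatwave_exposure(hw, s$pop, g, 1986:2005, 2011:2015))
    t$value[t$indicator_id == paste0("heatwave_person_days_", g) &
              t$region == "GLOBAL"]
  }, numeric(1))
  # recompute directly: total person-days = mean annual counts x all-age pop
  ann <- rowsum(climind:::field_matrix(hw), hw$years)
  cnt <- colMeans(ann[as.integer(rownames(ann)) %in% 2011:2015, , drop = FALSE])
  allpop <- colSums(matrix(s$pop$counts, nrow = length(s$pop$age_groups)))
  expect_equal(sum(total_by_group), sum(cnt * allpop))
})

test_that("hourly reconstruction and WBGT follow the closed forms", {
  expect_equal(hourly_temperature(10, 20, 6), 10)
  expect_equal(hourly_temperature(10, 20, 15), 20)
  expect_true(all(diff(sapply(6:15, hourly_temperature, tmin = 10, tmax = 20)) >= 0))
  e <- 50 / 100 * 6.105 * exp(17.27 * 30 / (237.7 + 30))
  expect_equal(wbgt(30, 50), 0.567 * 30 + 0.393 * e + 3.94)
  expect_error(wbgt(30, 130), "RH")
})

test_that("risk hours saturate at 8760 and vanish in cold conditions", {
  years <- 2000L
  cold_min <- make_field(-20, "tmin", years = years)
  cold_max <- make_field(-10, "tmax", years = years)
  hot_min <- make_field(35, "tmin", years = years)
  hot_max <- make_field(45, "tmax", years = years)
  rh <- make_field(50, "rh", "%", years = years)
  pop <- population_grid(cold_min$lats, cold_min$lons, "all",
                         array(1, c(1, 2, 2)))
  tc <- as.data.frame(wbgt_risk_hours(cold_min, cold_max, rh, pop))
  expect_true(all(tc$value == 0))
  th <- as.data.frame(wbgt_risk_hours(hot_min, hot_max, rh, pop))
  expect_true(all(th$value == 24 * 365))
})

test_that("work ability has the stated midpoint, bounds and monotonicity", {
  expect_equal(work_ability(34.64, 34.64, 22.72), 0.55)
  sweep_w <- seq(0, 60, by = 0.05)
  loss <- 1 - work_ability(sweep_w, 32.98, 17.81)
  expect_true(all(diff(loss) >= 0))
  expect_true(all(loss >= 0 & loss <= 0.9))
  expect_lt(loss[sweep_w == 10], 1e-6)
  expect_gt(loss[length(loss)], 0.89)
})

test_that("labour hours lost scale linearly with workers and report shares", {
  years <- 2000L
  tmin <- make_field(30, "tmin", years = years)
  tmax <- make_field(38, "tmax", years = years)
  rh <- make_field(60, "rh", "%", years = years)
  counts <- array(0, c(4, 2, 2))
  counts[1, 1, 1] <- 1000   # agriculture only
  workers <- population_grid(tmin$lats, tmin$lons,
                             c("agriculture", "construction",
                               "manufacturing", "services"), counts)
  res <- labour_hours_lost(tmin, tmax, rh, workers)
  tab <- as.data.frame(res$table)
  tot <- tab$value[tab$indicator_id == "labour_hours_lost_total"]
  ag <- tab$value[tab$indicator_id == "labour_hours_lost_agriculture"]
  expect_equal(ag, tot)
  expect_equal(tab$value[tab$indicator_id == "labour_hours_lost_agriculture_share"], 1)
  counts2 <- counts; counts2[1, 1, 1] <- 2000
  res2 <- labour_hours_lost(tmin, tmax, rh,
                            population_grid(tmin$lats, tmin$lons,
                                            workers$age_groups, counts2))
  tot2 <- as.data.frame(res2$table)
  expect_equal(tot2$value[tot2$indicator_id == "labour_hours_lost_total"], 2 * tot)
})

test_that("mortality attribution matches the closed form and is monotone", {
  years <- 2000:2001
  nt <- 730L
  vals <- array(20, dim = c(nt, 1, 1))
  vals[400L, 1, 1] <- 22  # one day 2 degC above threshold
  f <- climate_field("tmean", "degC", rep(years, each = 365L),
                     rep(1:365, 2), 5, 0, vals)
  cl <- build_percentile_climatology(
    make_field(20, lats = 5, lons = 0, years = 2000L), c(2000L, 2000L), 0.95)
  pop <- population_grid(5, 0, "65plus", array(1000, c(1, 1, 1)))
  regions <- region_table(data.frame(
    cell_table(5, 0), country_code = "AAA", hdi_group = "high",
    elevation_m = 100, is_land = TRUE, is_coastal = FALSE,
    land_class = "cropland", urban_centre_id = NA_integer_, ndvi = 0.5))
  mk <- function(beta) mortality_er_params(0.95, beta,
                                           baseline_deaths = c(AAA = 365 * 100))
  res <- heat_attributable_mortality(f, cl, pop, regions, mk(0.05),
                                     period1 = 2000L, period2 = 2001L)
  d <- as.data.frame(res$table)
  deaths_2001 <- d$value[d$indicator_id == "heat_attributable_deaths" &
                           d$region == "AAA"]
  expect_equal(deaths_2001, (1 - exp(-0.05 * 2)) * 100, tolerance = 1e-12)
  # zero under beta = 0
  res0 <- heat_attributable_mortality(f, cl, pop, regions, mk(0))
  expect_true(all(as.data.frame(res0$table)$value == 0, na.rm = TRUE))
  # monotone in beta and in pointwise warming
  res2 <- heat_attributable_mortality(f, cl, pop, regions, mk(0.1),
                                      period1 = 2000L, period2 = 2001L)
  d2 <- as.data.frame(res2$table)
  expect_gt(d2$value[d2$indicator_id == "heat_attributable_deaths" &
                       d2$region == "AAA"], deaths_2001)
  vals_w <- vals + 0.5
  fw <- climate_field("tmean", "degC", f$years, f$doys, f$lats, f$lons, vals_w)
  resw <- heat_attributable_mortality(fw, cl, pop, regions, mk(0.05),
                                      period1 = 2000L, period2 = 2001L)
  dw <- as.data.frame(resw$table)
  expect_gt(dw$value[dw$indicator_id == "heat_attributable_deaths" &
                       dw$region == "AAA"], deaths_2001)
  expect_error(mortality_er_params(beta_mort = -1), "beta_mort")
})
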