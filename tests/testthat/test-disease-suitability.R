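make_region_fixture <- function(lats = c(0, 40), lons = c(0, 10),
                                elevation = 100, coastal = FALSE,
                                land_class = "cropland") {
  ct <- cell_table(lats, lons)
  region_table(data.frame(
    ct, country_code = "AAA", hdi_group = "medium", elevation_m = elevation,
    is_land = TRUE, is_coastal = coastal, land_class = land_class,
    urban_centre_id = NA_integer_, ndvi = 0.4))
}

test_that("R0 vanishes without vector density and is continuous in T", {
  p <- dengue_params()
  p$m0 <- 0
  sweep_t <- seq(5, 45, by = 0.1)
  expect_true(all(dengue_r0(sweep_t, 100, p) == 0))
  p2 <- dengue_params()
  r0 <- dengue_r0(sweep_t, 100, p2)
  expect_true(all(r0 >= 0))
  expect_true(all(abs(diff(r0)) < 0.5))  # no jumps on a 0.1 degC grid
})

test_that("R0 temperature response is unimodal with the oracle's maximum", {
  p <- dengue_params()
  sweep_t <- seq(10, 40, by = 0.1)
  r0 <- dengue_r0(sweep_t, 1000, p)
  # independent re-evaluation of the closed form from the coefficient file
  coefs <- read.csv(system.file("extdata", "dengue_coefficients_aegypti.csv",
                                package = "climind"))
  cv <- function(fn, term) as.numeric(coefs$value[coefs[[1]] == fn &
                                                    coefs$term == term])
  br <- function(T, f) {
    out <- cv(f, "c") * T * (T - cv(f, "tmin")) * sqrt(pmax(cv(f, "tmax") - T, 0))
    ifelse(T > cv(f, "tmin") & T < cv(f, "tmax"), out, 0)
  }
  lf <- pmax(cv("lifespan", "c") * (sweep_t - cv("lifespan", "tmin")) *
               (cv("lifespan", "tmax") - sweep_t), 0.01)
  mu <- 1 / lf
  pdr <- br(sweep_t, "pdr")
  oracle <- sqrt(2 * pmin(1000 / 80, 1) * br(sweep_t, "biting_rate")^2 *
                   pmin(br(sweep_t, "prob_vector_to_human"), 1) *
                   pmin(br(sweep_t, "prob_human_to_vector"), 1) *
                   ifelse(pdr > 0, exp(-mu / pdr), 0) / (mu * 0.2))
  expect_equal(r0, oracle)
  imax <- which.max(r0)
  expect_equal(sweep_t[imax], sweep_t[which.max(oracle)])
  expect_gt(imax, 1); expect_lt(imax, length(sweep_t))  # interior maximum
  # unimodal: increasing then decreasing over the support
  supp <- which(r0 > 0)
  d <- diff(r0[supp])
  expect_lte(length(rle(sign(d))$values[rle(sign(d))$values != 0]), 2L)
})

test_that("identical decades give exactly zero R0 change", {
  tm <- make_monthly(seq(18, 29, by = 1), years = 2000:2009)
  pm <- make_monthly(rep(100, 12), years = 2000:2009, variable = "precip",
                     units = "mm")
  pop <- population_grid(tm$lats, tm$lons, "all", array(1, c(1, 2, 2)))
  tab <- as.data.frame(dengue_r0_suitability(tm, pm, pop, dengue_params(),
                                             2000:2009, 2000:2009))
  expect_equal(tab$value[tab$indicator_id == "dengue_r0_change"], 0)
})

test_that("malaria month rules implement the threshold conjunction", {
  regions <- make_region_fixture()
  tm <- make_monthly(rep(25, 12))                       # inside [18, 32)
  pm <- make_monthly(rep(100, 12), variable = "precip", units = "mm")
  hm <- make_monthly(rep(70, 12), variable = "rh", units = "%")
  tab <- as.data.frame(malaria_suitable_months(tm, pm, hm, regions,
                                               malaria_thresholds(),
                                               2000L, 2000L))
  expect_equal(tab$value[tab$indicator_id == "malaria_suitable_months" &
                           tab$period == "2000"][1], 12)
  # zero precipitation kills suitability regardless of T, RH
  pm0 <- make_monthly(rep(0, 12), variable = "precip", units = "mm")
  t0 <- as.data.frame(malaria_suitable_months(tm, pm0, hm, regions,
                                              malaria_thresholds(), 2000L, 2000L))
  expect_equal(t0$value[t0$indicator_id == "malaria_suitable_months" &
                          t0$period == "2000"][1], 0)
  # lower temperature bound is inclusive
  tmb <- make_monthly(rep(18, 12))
  tb <- as.data.frame(malaria_suitable_months(tmb, pm, hm, regions,
                                              malaria_thresholds(), 2000L, 2000L))
  expect_equal(tb$value[tb$indicator_id == "malaria_suitable_months" &
                          tb$period == "2000"][1], 12)
  # upper bound is exclusive
  tmx <- make_monthly(rep(32, 12))
  tx <- as.data.frame(malaria_suitable_months(tmx, pm, hm, regions,
                                              malaria_thresholds(), 2000L, 2000L))
  expect_equal(tx$value[tx$indicator_id == "malaria_suitable_months" &
                          tx$period == "2000"][1], 0)
})

test_that("malaria suitability is monotone in each threshold", {
  s <- small_scenario()
  tm <- monthly_climate(s$fields$tmean, "mean")
  pm <- monthly_climate(s$fields$precip, "sum")
  hm <- monthly_climate(s$fields$rh, "mean")
  months_at <- function(thr) {
    t <- as.data.frame(malaria_suitable_months(tm, pm, hm, s$regions, thr,
                                               1986:1995, 2006:2015))
    t$value[t$indicator_id == "malaria_suitable_months" & t$period == "2006-2015"]
  }
  base <- months_at(malaria_thresholds())
  expect_lte(months_at(malaria_thresholds(precip_min = 120)), base)
  expect_lte(months_at(malaria_thresholds(rh_min = 75)), base)
  expect_lte(months_at(malaria_thresholds(t_min = 20, t_max = 30)), base)
  # restricting land classes can only reduce the (area-weighted) mean
  expect_lte(months_at(malaria_thresholds(land_class_mask = "cropland")),
             months_at(malaria_thresholds(land_class_mask = c("cropland",
                                                              "forest",
                                                              "grassland",
                                                              "shrubland"))))
})

test_that("vibrio suitability applies both gates and the run rule", {
  lats <- 50; lons <- c(0, 10)
  ct <- cell_table(lats, lons)
  regions <- region_table(data.frame(
    ct, country_code = "AAA", hdi_group = "high", elevation_m = 1,
    is_land = TRUE, is_coastal = TRUE, land_class = "cropland",
    urban_centre_id = NA_integer_, ndvi = 0.2))
  mk <- function(sst_val, sss_val) {
    list(sst = make_field(sst_val, "sst", "degC", lats, lons, 2000L),
         sss = make_field(sss_val, "sss", "psu", lats, lons, 2000L))
  }
  f <- mk(25, 10)
  t1 <- as.data.frame(vibrio_coastal_suitability(f$sst, f$sss, regions,
                                                 vibrio_thresholds(),
                                                 2000L, 2000L))
  expect_equal(t1$value[t1$indicator_id == "vibrio_coastal_suitability"][1], 100)
  # salinity gate: fully saline water is never suitable
  fs <- mk(25, 35)
  t2 <- as.data.frame(vibrio_coastal_suitability(fs$sst, fs$sss, regions,
                                                 vibrio_thresholds(),
                                                 2000L, 2000L))
  expect_equal(t2$value[t2$indicator_id == "vibrio_coastal_suitability"][1], 0)
  # a 4-day warm spell fails min_run_days 5 but passes min_run_days 4
  sstv <- array(10, dim = c(365L, 1L, 2L))
  sstv[100:103, 1, ] <- 25
  sst4 <- climate_field("sst", "degC", rep(2000L, 365L), 1:365, lats, lons, sstv)
  sss <- make_field(10, "sss", "psu", lats, lons, 2000L)
  r5 <- as.data.frame(vibrio_coastal_suitability(sst4, sss, regions,
                                                 vibrio_thresholds(min_run_days = 5L),
                                                 2000L, 2000L))
  r4 <- as.data.frame(vibrio_coastal_suitability(sst4, sss, regions,
                                                 vibrio_thresholds(min_run_days = 4L),
                                                 2000L, 2000L))
  expect_equal(r5$value[r5$indicator_id == "vibrio_coastal_suitability"][1], 0)
  expect_equal(r4$value[r4$indicator_id == "vibrio_coastal_suitability"][1], 100)
  # latitude band with no coastal cells is an error
  expect_error(vibrio_coastal_suitability(f$sst, f$sss, regions,
                                          vibrio_thresholds(latitude_band = c(-70, -40)),
                                          2000L, 2000L),
               "no coastal cells")
})

test_that("warming increases dengue suitability in a temperate scenario", {
  s <- small_scenario()
  tm <- monthly_climate(s$fields$tmean, "mean")
  pm <- monthly_climate(s$fields$precip, "sum")
  tab <- as.data.frame(dengue_r0_suitability(tm, pm, s$pop, dengue_params(),
                                             1986:1995, 2006:2015))
  expect_gt(tab$value[tab$indicator_id == "dengue_r0_change"], 0)
})
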