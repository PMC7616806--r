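test_that("monthly aggregation averages and sums correctly", {
  f <- make_field(2, "precip", "mm", years = 2000L)
  mm <- monthly_climate(f, "sum")
  expect_equal(as.vector(mm$values[1, 1, 1]), 2 * 31)   # January total
  expect_equal(as.vector(mm$values[2, 1, 1]), 2 * 28)   # February (no leap)
  tm <- monthly_climate(f, "mean")
  expect_true(all(tm$values == 2))
})

test_that("Thornthwaite PET matches direct evaluation of its equations", {
  # all twelve months at 20 degC and no day-length correction
  mf <- make_monthly(rep(20, 12))
  pet <- thornthwaite_pet(mf, correction = "none")
  I <- 12 * (20 / 5)^1.514
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  expected <- 16 * (10 * 20 / I)^a
  expect_equal(as.vector(pet$values[1, 1, 1]), expected)
  expect_equal(expected, 73.8, tolerance = 0.005)
  # cold branch: PET identically zero
  cold <- make_monthly(rep(-5, 12))
  expect_true(all(thornthwaite_pet(cold)$values == 0))
  # day-length correction is a per-month multiplicative factor
  pet_c <- thornthwaite_pet(mf, correction = "daylength")
  ratio <- pet_c$values / pet$values
  for (mo in 1:12) expect_equal(length(unique(round(ratio[mo, 1, ], 10))), 1L)
})

test_that("log-logistic L-moment fit is exact on its own L-moments", {
  # distribution function inverts the quantile map
  q <- rloglogistic(5, 40, 5, 10)
  expect_equal(ploglogistic(q, 40, 5, 10),
               1 / (1 + (40 / (q - 10))^5))
  # degenerate sample yields NA parameters
  expect_true(all(is.na(fit_loglogistic(rep(3, 30)))))
})

test_that("fitted log-logistic reproduces the generating distribution", {
  set.seed(61)
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  qtrue <- 10 + 40 * (qs / (1 - qs))^(1 / 5)
  err <- replicate(10, {
    x <- rloglogistic(600, 40, 5, 10)
    f <- fit_loglogistic(x)
    qfit <- f[["location"]] + f[["scale"]] * (qs / (1 - qs))^(1 / f[["shape"]])
    max(abs(qfit - qtrue) / qtrue)
  })
  expect_lt(mean(err), 0.05)
})

test_that("normal quantile approximation is accurate and antisymmetric", {
  p <- c(0.001, 0.0548, 0.25, 0.5, 0.75, 0.9452, 0.999)
  expect_equal(std_normal_quantile(p), qnorm(p), tolerance = 2e-3)
  poff <- p[p != 0.5]  # the two branches mirror exactly away from the median
  expect_equal(std_normal_quantile(poff), -std_normal_quantile(1 - poff),
               tolerance = 1e-12)
})

test_that("SPEI is standardised over its calibration period", {
  s <- small_scenario()
  tm <- monthly_climate(s$fields$tmean, "mean")
  pm <- monthly_climate(s$fields$precip, "sum")
  pet <- thornthwaite_pet(tm)
  sx <- spei(pm, pet, spei_params())
  m <- climind:::monthly_matrix(sx)
  mu <- colMeans(m, na.rm = TRUE)
  sd_ <- apply(m, 2, sd, na.rm = TRUE)
  expect_true(all(abs(mu) < 0.05))
  expect_true(all(abs(sd_ - 1) < 0.1))
  # only the spin-up months are missing
  expect_equal(sum(is.na(m[, 1])), 5L)
})

test_that("SPEI is invariant to a constant shift of the water balance", {
  s <- small_scenario()
  tm <- monthly_climate(s$fields$tmean, "mean")
  pm <- monthly_climate(s$fields$precip, "sum")
  pet <- thornthwaite_pet(tm)
  s1 <- spei(pm, pet, spei_params())
  pm2 <- pm
  pm2$values <- pm$values + 50  # uniformly wetter, same shape
  s2 <- spei(pm2, pet, spei_params())
  expect_equal(s2$values, s1$values, tolerance = 1e-6)
})

test_that("extreme drought area follows hand-computed fractions", {
  # 2x2 grid, all land, equal-ish areas at one latitude
  lats <- c(5, 5.5); lons <- c(0, 10)
  ct <- cell_table(lats, lons)
  regions <- region_table(data.frame(
    ct, country_code = "AAA", hdi_group = "low", elevation_m = 100,
    is_land = TRUE, is_coastal = FALSE, land_class = "cropland",
    urban_centre_id = NA_integer_, ndvi = 0.3))
  base <- array(0, dim = c(24L, 2L, 2L))
  mk <- function(arr) structure(list(variable = "spei", units = "dimensionless",
                                     years = rep(2000:2001, each = 12L),
                                     months = rep(1:12, 2L), lats = lats,
                                     lons = lons, values = arr),
                                class = "monthly_field")
  p <- spei_params(reference_decade = 2000L, comparison_decade = 2001L)
  expect_true(all(as.data.frame(extreme_drought_area(mk(base), regions, p))$value[1:2] == 0))
  hit <- base
  hit[13L, , ] <- -2        # January of 2001, all cells
  t1 <- as.data.frame(extreme_drought_area(mk(hit), regions, p))
  expect_equal(t1$value[t1$indicator_id == "extreme_drought_area" &
                          t1$period == "2001"], 100)
  # 2 of 4 cells affected at (almost) equal area: ~50%
  half <- base
  half[13L, 1, ] <- -2      # both cells of the first latitude row
  t2 <- as.data.frame(extreme_drought_area(mk(half), regions, p))
  v <- t2$value[t2$indicator_id == "extreme_drought_area" & t2$period == "2001"]
  w <- cos(c(5, 5.5) * pi / 180)
  expect_equal(v, 100 * w[1] / sum(w))
  # monotone non-increasing as the threshold is lowered
  p_deep <- spei_params(extreme_threshold = -3,
                        reference_decade = 2000L, comparison_decade = 2001L)
  t3 <- as.data.frame(extreme_drought_area(mk(half), regions, p_deep))
  expect_lte(t3$value[t3$indicator_id == "extreme_drought_area" &
                        t3$period == "2001"], v)
})

test_that("crop season length matches the constant-temperature closed form", {
  cp <- crop_params(data.frame(crop = "test", sowing_doy_nh = 1L,
                               sowing_doy_sh = 1L, gdd_requirement = 1000,
                               t_base = 10, t_cap = 30))
  f <- make_field(20, years = 2000:2001)  # 10 GDD per day
  res <- crop_season_length(f, cp, "test")
  expect_true(all(res$lengths[1, ] == 100))
  # capping binds: T far above cap, cap - base = 20 -> ceil(1000/20) = 50
  fhot <- make_field(80, years = 2000:2001)
  res2 <- crop_season_length(fhot, cp, "test")
  expect_true(all(res2$lengths[1, ] == ceiling(1000 / 20)))
  # cold: requirement never met within 365 days -> censored (NA), flagged
  fcold <- make_field(10, years = 2000:2001)
  res3 <- crop_season_length(fcold, cp, "test")
  expect_true(all(is.na(res3$lengths[1, ])))
  expect_equal(res3$censored_fraction, 1)
})

test_that("warming never lengthens the growing season", {
  set.seed(31)
  cp <- crop_params(data.frame(crop = "test", sowing_doy_nh = 60L,
                               sowing_doy_sh = 240L, gdd_requirement = 800,
                               t_base = 5, t_cap = 28))
  vals <- 12 + 8 * sin(2 * pi * (1:730) / 365) + rnorm(730, sd = 2)
  f <- make_field(rep(vals, each = 1), years = 2000:2001)
  f$values <- array(rep(vals, 4), dim = c(730, 2, 2))
  warm <- f; warm$values <- f$values + 1
  l0 <- crop_season_length(f, cp, "test")$lengths
  l1 <- crop_season_length(warm, cp, "test")$lengths
  expect_true(all(l1 <= l0, na.rm = TRUE))
})

test_that("coastal SST change averages the per-cell changes", {
  lats <- 5; lons <- c(0, 10)
  ct <- cell_table(lats, lons)
  regions <- region_table(data.frame(
    ct, country_code = "AAA", hdi_group = "low", elevation_m = 1,
    is_land = TRUE, is_coastal = TRUE, land_class = "cropland",
    urban_centre_id = NA_integer_, ndvi = 0.3))
  vals <- array(10, dim = c(730L, 1L, 2L))
  vals[366:730, 1, 1] <- 10.4
  vals[366:730, 1, 2] <- 11.0
  f <- climate_field("sst", "degC", rep(2000:2001, each = 365L),
                     rep(1:365, 2L), lats, lons, vals)
  tab <- as.data.frame(coastal_sst_anomaly(f, regions, 2000L, 2001L))
  expect_equal(tab$value[tab$region == "AAA"], 0.7)
  expect_equal(tab$value[tab$region == "GLOBAL"], 0.7)
  # identical periods give exactly zero
  t0 <- as.data.frame(coastal_sst_anomaly(f, regions, 2000L, 2000L))
  expect_true(all(t0$value == 0))
})
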