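test_that("fit_slope matches difference quotients and closed-form OLS", {
  f <- fit_slope(c(0, 12), c(400, 412))
  expect_equal(f$slope_ppmv_h, 1)
  expect_equal(f$r_squared, 1)

  expect_equal(fit_slope(c(0, 12, 18), c(400, 400, 400))$slope_ppmv_h, 0)

  f3 <- fit_slope(c(0, 12, 18), c(400, 406, 409))
  expect_equal(f3$slope_ppmv_h, 0.5)
  expect_equal(f3$r_squared, 1)
  expect_equal(f3$n_points, 3L)

  # oracle equivalence on random non-collinear points
  set.seed(11)
  for (i in 1:20) {
    t <- sort(runif(4, 0, 18))
    y <- 400 + runif(1, -2, 2) * t + rnorm(4)
    fit <- lm(y ~ t)
    got <- fit_slope(t, y)
    expect_equal(got$slope_ppmv_h, unname(coef(fit)[2]), tolerance = 1e-12)
    expect_equal(got$r_squared, summary(fit)$r.squared, tolerance = 1e-12)
  }
  expect_error(fit_slope(c(0, 0), c(1, 2)), "distinct")
})

test_that("mean_kelvin averages in-window readings with nearest fallback", {
  ts <- data.frame(time_h = c(0, 12), temp_C = c(24.2, 33.6))
  expect_equal(mean_kelvin(ts, c(0, 12)), (24.2 + 33.6) / 2 + 273.15)
  expect_equal(mean_kelvin(data.frame(time_h = 0, temp_C = 0)), 273.15)
  # window past the log -> nearest reading to the window midpoint
  ts2 <- data.frame(time_h = c(0, 5), temp_C = c(20, 25))
  expect_equal(mean_kelvin(ts2, c(8, 10)), 25 + 273.15)
  expect_error(mean_kelvin(data.frame(time_h = numeric(0),
                                      temp_C = numeric(0))),
               "empty")
})

test_that("compute_flux equals the hand ideal-gas oracle", {
  cc <- flux_constants()
  # n = PV/RT = 0.0246 / (8.205746e-5 * 300) mol; F = slope * n / A
  geom <- chamber_geometry(area_m2 = 1, headspace_volume_L = 24.6)
  s <- gas_series("CO2", c(0, 12), c(400, 412))  # slope 1 ppmv/h
  r <- compute_flux(s, geom, const_temp(300 - 273.15))
  n_oracle <- 1 * 0.0246 / (8.205746e-5 * 300)
  expect_equal(r$flux_umol_m2_h, n_oracle, tolerance = 1e-9)
  expect_equal(r$flux_umol_m2_h, 0.9993, tolerance = 1e-4)

  # doubling the area exactly halves the flux
  geom2 <- chamber_geometry(area_m2 = 2, headspace_volume_L = 24.6)
  r2 <- compute_flux(s, geom2, const_temp(300 - 273.15))
  expect_equal(r2$flux_umol_m2_h, r$flux_umol_m2_h / 2)

  # zero slope -> zero flux regardless of geometry
  s0 <- gas_series("CO2", c(0, 12, 18), rep(400, 3))
  expect_equal(compute_flux(s0, geom, const_temp(25))$flux_umol_m2_h, 0)
})

test_that("flux obeys the ideal-gas scaling laws", {
  set.seed(21)
  tt <- c(0, 12, 18)
  for (i in 1:25) {
    slope <- runif(1, -2, 2)
    A <- runif(1, 0.05, 1)
    V <- runif(1, 1, 30)
    temp <- runif(1, 5, 35)
    s <- gas_series("CO2", tt, 400 + slope * tt)
    base <- compute_flux(s, chamber_geometry(A, V), const_temp(temp))
    # linear in slope (sign preserved), linear in V, inverse in A
    expect_equal(sign(base$flux_umol_m2_h), sign(slope))
    dblV <- compute_flux(s, chamber_geometry(A, 2 * V), const_temp(temp))
    expect_equal(dblV$flux_umol_m2_h, 2 * base$flux_umol_m2_h,
                 tolerance = 1e-12)
    dblA <- compute_flux(s, chamber_geometry(2 * A, V), const_temp(temp))
    expect_equal(dblA$flux_umol_m2_h, base$flux_umol_m2_h / 2,
                 tolerance = 1e-12)
    hot <- compute_flux(s, chamber_geometry(A, V), const_temp(temp + 10))
    if (slope != 0)
      expect_lt(abs(hot$flux_umol_m2_h), abs(base$flux_umol_m2_h))
  }
})

test_that("CH4 fluxes carry a mass scale that round-trips", {
  cc <- flux_constants()
  s <- gas_series("CH4", c(0, 12), c(2, 2.6))
  r <- compute_flux(s, chamber_geometry(0.1, 2), const_temp(28))
  expect_equal(r$flux_ug_m2_h / cc$CH4_molar_mass, r$flux_umol_m2_h,
               tolerance = 1e-12)
})

test_that("degraded series yield statuses, not exceptions", {
  geom <- chamber_geometry(0.1, 2)
  all_nd <- gas_series("CH4", c(0, 12, 18), rep(NA_real_, 3),
                       detected = rep(FALSE, 3))
  r <- compute_flux(all_nd, geom, const_temp(28))
  expect_equal(r$status, "nondetect")
  expect_true(is.na(r$flux_umol_m2_h) && is.na(r$slope_ppmv_h))

  one <- gas_series("CH4", c(0, 12, 18), c(2.2, NA, NA),
                    detected = c(TRUE, FALSE, FALSE))
  expect_equal(compute_flux(one, geom, const_temp(28))$status,
               "insufficient_points")
})

test_that("per-interval fluxes cover consecutive pairs and flag gaps", {
  geom <- chamber_geometry(0.1, 2)
  tt <- c(0, 12, 18)
  s <- gas_series("CO2", tt, c(400, 406, 406))
  res <- flux_by_interval(s, geom, const_temp(28))
  expect_length(res, 2L)
  expect_equal(vapply(res, `[[`, "", "interval"), c("t0-t1", "t1-t2"))
  expect_equal(res[[1]]$slope_ppmv_h, 0.5)
  expect_equal(res[[2]]$flux_umol_m2_h, 0)  # equal endpoints

  # damaged chamber at t2: the t1-t2 interval leaves a skip record
  dmg <- gas_series("CO2", tt, c(400, 406, NA),
                    detected = c(TRUE, TRUE, FALSE))
  res2 <- flux_by_interval(dmg, geom, const_temp(28))
  expect_equal(res2[[1]]$status, "ok")
  expect_equal(res2[[2]]$status, "insufficient_points")
})

test_that("whole-series flux uses the 3-point OLS slope, not interval means", {
  geom <- chamber_geometry(0.1, 2)
  s <- gas_series("CO2", c(0, 12, 18), c(400, 401, 409))
  whole <- compute_flux(s, geom, const_temp(28))
  ols <- fit_slope(c(0, 12, 18), c(400, 401, 409))$slope_ppmv_h
  expect_equal(whole$slope_ppmv_h, ols)
  ivals <- flux_by_interval(s, geom, const_temp(28))
  expect_false(isTRUE(all.equal(
    whole$slope_ppmv_h,
    mean(vapply(ivals, `[[`, 1, "slope_ppmv_h")))))
})
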