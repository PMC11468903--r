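test_that("simulation is a deterministic function of the seed", {
  a <- simulate_study(simulation_config(seed = 5))
  b <- simulate_study(simulation_config(seed = 5))
  c <- simulate_study(simulation_config(seed = 6))
  expect_identical(a, b)
  expect_false(identical(a$bare_sand_1$gas_series$CO2$conc_ppmv,
                         c$bare_sand_1$gas_series$CO2$conc_ppmv))
  # chambers within one study carry decorrelated noise
  expect_false(identical(a$bare_sand_1$gas_series$CO2$conc_ppmv,
                         a$bare_sand_2$gas_series$CO2$conc_ppmv))
})

test_that("zero-noise chambers invert to the configured ground truth", {
  cfg <- clean_config(seed = 9)
  st <- simulate_study(cfg)
  expect_length(st, 9L)
  for (d in st) {
    truth <- cfg$true_flux_umol[[sub("_[0-9]+$", "", d$chamber_id)]]
    for (g in c("CO2", "CH4")) {
      r <- compute_flux(d$gas_series[[g]], d$geometry,
                        d$temperature_series)
      expect_lt(abs(r$flux_umol_m2_h - truth[[g]]), 1e-9)
      expect_equal(r$r_squared, 1)
    }
    m <- hourly_metabolism(d$do_series, cfg$water_volume_L,
                           cfg$geometry$area_m2)
    expect_equal(m$cr_hourly, cfg$r_hourly, tolerance = 1e-9)
    expect_equal(m$ncp_hourly, cfg$p_hourly + cfg$r_hourly,
                 tolerance = 1e-9)
    expect_identical(m$gpp_hourly, m$cr_hourly + m$ncp_hourly)
  }
})

test_that("flat world: zero rates give flat DO and zero flux", {
  cfg <- clean_config(seed = 2, r_hourly = 0, p_hourly = 0,
                      true_flux_umol = list(
                        bare_sand = c(CO2 = 0, CH4 = 0),
                        E_acoroides = c(CO2 = 0, CH4 = 0),
                        T_hemprichii = c(CO2 = 0, CH4 = 0)))
  d <- simulate_study(cfg)[[1]]
  expect_equal(diff(d$do_series$do_mg_L), c(0, 0), tolerance = 1e-12)
  expect_equal(diff(d$gas_series$CO2$conc_ppmv), c(0, 0),
               tolerance = 1e-12)
})

test_that("sub-detection CH4 yields non-detects, never zeros", {
  # bare-sand CH4 flux 0 and ambient C0 well below the detection limit
  # at this noise level, so the area is genuinely sub-detection
  cfg <- simulation_config(seed = 3, gas_noise_sd = 0.1)
  st <- simulate_study(cfg)
  bare <- st[grep("^bare", names(st))]
  for (d in bare) {
    s <- d$gas_series$CH4
    expect_true(all(!s$detected))
    expect_true(all(is.na(s$conc_ppmv)))
    r <- compute_flux(s, d$geometry, d$temperature_series)
    expect_equal(r$status, "nondetect")
    expect_true(is.na(r$flux_umol_m2_h))
  }
  # vegetated areas accumulate past the limit and are quantifiable
  veg <- st[grep("acoroides", names(st))]
  for (d in veg)
    expect_gte(sum(d$gas_series$CH4$detected), 2)
})

test_that("study layout follows the configuration", {
  st <- simulate_study(simulation_config(seed = 1))
  expect_length(st, 9L)
  expect_equal(sum(vapply(st, function(d) d$area_type == "bare", TRUE)),
               3L)
  expect_length(simulate_study(simulation_config(
    seed = 1, n_chambers_per_area = 0)), 0L)
})

test_that("end-to-end: simulate -> write -> read -> flux -> stats", {
  cfg <- simulation_config(
    seed = 13, gas_noise_sd = 0.05,
    true_flux_umol = list(bare_sand = c(CO2 = 0.02, CH4 = 0),
                          E_acoroides = c(CO2 = 0.2, CH4 = 0.13),
                          T_hemprichii = c(CO2 = 0.2, CH4 = 0.084)))
  dir <- withr::local_tempdir()
  write_study(simulate_study(cfg), dir, cfg)
  expect_true(file.exists(file.path(dir, "truth.csv")))
  deps <- read_deployments(file.path(dir, "deployments.csv"))
  expect_length(deps, 9L)
  tlog <- read_temperature_log(file.path(dir, "temperature.csv"))
  deps <- attach_temperature(deps, tlog)
  ft <- study_fluxes(deps)
  co2 <- ft[ft$gas == "CO2" & ft$interval == "all", ]
  # configured 10x vegetated/bare effect is detected by the ANOVA
  res <- compare_groups(co2, "flux_umol_m2_h", "area_type")
  expect_lt(res$summary$p, 0.05)
  means <- area_mean_fluxes(ft)
  veg <- means$mean_flux_umol_m2_h[means$area_type == "vegetated" &
                                     means$gas == "CO2"]
  bare <- means$mean_flux_umol_m2_h[means$area_type == "bare" &
                                      means$gas == "CO2"]
  expect_gt(veg, bare)
  # metabolism table runs on the re-read deployments too
  mt <- study_metabolism(deps)
  expect_equal(nrow(mt), 9L)
  expect_identical(mt$gpp_hourly_mmol_m2_h,
                   mt$cr_hourly_mmol_m2_h + mt$ncp_hourly_mmol_m2_h)
})
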