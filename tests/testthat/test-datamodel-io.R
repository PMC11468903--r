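test_that("constants validate and carry the standard defaults", {
  cc <- flux_constants()
  expect_equal(cc$R_gas, 8.205746e-5)
  expect_equal(cc$P_atm, 1)
  expect_equal(cc$O2_molar_mass, 32)
  expect_identical(c(cc$PQ, cc$RQ), c(1, 1))
  expect_true(cc$SGWP_CH4 >= 45 && cc$SGWP_CH4 <= 96)
  expect_error(flux_constants(P_atm = -1), "positive")
  expect_warning(flux_constants(SGWP_CH4 = 100), "outside")
})

test_that("geometry and series constructors enforce their invariants", {
  expect_error(chamber_geometry(0, 1), "area_m2")
  expect_error(chamber_geometry(1, -2), "headspace")
  expect_error(chamber_geometry(1, 1, chamber_length_cm = 61.5,
                                insertion_depth_cm = 70),
               "insertion_depth")
  expect_error(gas_series("CO2", c(0, 12, 12), c(1, 2, 3)),
               "strictly increasing")
  expect_error(gas_series("CO2", c(0, 12), c(400, -1)), ">= 0")
  expect_error(do_series(c(0, 12), c(8, -1)), ">= 0")
  # non-detect samples carry no usable concentration
  s <- gas_series("CH4", c(0, 12, 18), c(2, NA, 2.4),
                  detected = c(TRUE, FALSE, TRUE))
  expect_true(is.na(s$conc_ppmv[2]))
  expect_error(chamber_deployment("x", "vegetated",
                                  chamber_geometry(1, 1),
                                  photoperiod_h = 25),
               "photoperiod")
})

test_that("deployments round-trip through the CSV dialect", {
  deps <- list(fixture_deployment("ch1", "vegetated", co2_slope = 0.5),
               fixture_deployment("ch2", "bare", co2_slope = 0.1))
  # give ch2 a CH4 series with one non-detect
  deps[[2]]$gas_series$CH4 <-
    gas_series("CH4", c(0, 12, 18), c(2, NA, 2.6),
               detected = c(TRUE, FALSE, TRUE))
  path <- write_fixture_csv(deps)
  back <- read_deployments(path)
  expect_named(back, c("ch1", "ch2"))
  expect_equal(back$ch1$area_type, "vegetated")
  expect_equal(back$ch2$gas_series$CH4$detected, c(TRUE, FALSE, TRUE))
  # numeric fields reproduced to >= 6 significant digits
  expect_equal(back$ch1$gas_series$CO2$conc_ppmv,
               deps[[1]]$gas_series$CO2$conc_ppmv, tolerance = 1e-9)
  expect_equal(back$ch1$do_series$do_mg_L, c(8.0, 6.4, 7.6))
  expect_equal(back$ch1$geometry$headspace_volume_L, 2)
  expect_equal(back$ch1$water_volume_L, 50)
})

test_that("reader rejects exactly the documented malformations", {
  dep <- list(fixture_deployment())
  path <- write_fixture_csv(dep)
  df <- utils::read.csv(path, colClasses = "character")

  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[, setdiff(names(df), "gas")], tmp, row.names = FALSE)
  expect_error(read_deployments(tmp), "gas")

  # out-of-order rows are re-sorted; duplicated times are non-monotone
  df2 <- df
  df2$time_h[df2$gas == "CO2"] <- c("0", "12", "12")
  write.csv(df2, tmp, row.names = FALSE)
  expect_error(read_deployments(tmp), "ch1")

  df3 <- df
  df3$conc_ppmv[1] <- "forty"
  write.csv(df3, tmp, row.names = FALSE)
  expect_error(read_deployments(tmp), "line")

  # header-only file is an empty study, not an error
  write.csv(df[0, ], tmp, row.names = FALSE)
  expect_identical(read_deployments(tmp), list())
})

test_that("temperature logs parse ISO timestamps and decimal hours", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,temp_C",
               "2023-06-14T18:00:00,28.0",
               "2023-06-15T06:00:00,24.2"), tmp)
  log <- read_temperature_log(tmp)
  expect_equal(log$time_h, c(0, 12))
  expect_equal(log$temp_C, c(28.0, 24.2))

  writeLines(c("timestamp,temp_C", "0,28.0"), tmp)
  expect_equal(nrow(read_temperature_log(tmp)), 1L)

  writeLines(c("timestamp,temp_C", "2023-06-14T18:00:00,28",
               "not a time,25"), tmp)
  expect_error(read_temperature_log(tmp), "row")

  writeLines(c("timestamp,temp_C", "12,28", "0,25"), tmp)
  expect_error(read_temperature_log(tmp), "order")
})

test_that("write_results emits deterministic, re-readable CSV", {
  dep <- fixture_deployment()
  dep$gas_series$CH4 <- gas_series("CH4", c(0, 12, 18),
                                   c(2, 2.5, 3.1))
  ft <- deployment_fluxes(dep)
  expect_setequal(unique(ft$gas), c("CO2", "CH4"))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_results(ft, tmp)
  back <- read_results(tmp)
  expect_identical(names(back), names(ft))
  expect_equal(back$flux_umol_m2_h, ft$flux_umol_m2_h, tolerance = 1e-9)
  # mixed-gas rows share the chamber id; empty table -> header only
  expect_true(all(back$chamber_id == "ch1"))
  write_results(ft[0, ], tmp)
  expect_equal(nrow(read_results(tmp)), 0L)
})
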