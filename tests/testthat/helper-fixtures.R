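# shared fixture builders -- everything is generated in code

const_temp <- function(temp_C = 28, times_h = c(0, 6, 12, 18)) {
  data.frame(time_h = times_h, temp_C = rep(temp_C, length(times_h)))
}

# a clean single-chamber deployment with known slopes
fixture_deployment <- function(chamber_id = "ch1", area_type = "vegetated",
                               co2_slope = 0.5, c0 = 420,
                               do = c(8.0, 6.4, 7.6),
                               temp_C = 28) {
  tt <- c(0, 12, 18)
  geom <- chamber_geometry(area_m2 = 0.1, headspace_volume_L = 2,
                           chamber_length_cm = 120,
                           insertion_depth_cm = 15)
  chamber_deployment(
    chamber_id = chamber_id, area_type = area_type,
    species_label = if (area_type == "vegetated") "E. acoroides" else "",
    geometry = geom, photoperiod_h = 12,
    temperature_series = const_temp(temp_C),
    gas_series = list(CO2 = gas_series("CO2", tt, c0 + co2_slope * tt)),
    do_series = do_series(tt, do),
    water_volume_L = 50, patch_area_ha = 0.15)
}

# deployments CSV text for read_deployments round trips
write_fixture_csv <- function(deployments, env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  write_study(deployments, dir)
  file.path(dir, "deployments.csv")
}

# zero-noise simulation config with full CH4 detection (no censoring)
clean_config <- function(seed = 1, ...) {
  simulation_config(seed = seed, gas_noise_sd = 0, do_noise_sd = 0,
                    detection_limit_ch4 = 0, ...)
}
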