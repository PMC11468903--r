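#' Configuration for the chamber-study forward simulator
#'
#' Defines the ground truth of a simulated benthic-chamber study:
#' per-area true gas fluxes, true hourly respiration and gross
#' production, noise levels, the sampling schedule and the chamber
#' set-up. Defaults emulate a tropical intertidal deployment: three
#' chambers per area on one bare-sand and two vegetated (seagrass)
#' areas, an 18-h incubation sampled at closure, after the 12-h dark
#' period and after 6 h of light, a diel temperature sinusoid spanning
#' 24.2--33.6 C, CO2 fluxes of order 0.01--0.14 umol m^-2 h^-1
#' (vegetated above bare), trace CH4 fluxes only in vegetated areas, and
#' CH4 held at/below the detection limit over bare sand.
#'
#' @param seed Integer RNG seed; the entire study is a deterministic
#'   function of it.
#' @param n_chambers_per_area Replicate chambers per area.
#' @param areas Named character vector, area label -> `"vegetated"` or
#'   `"bare"`.
#' @param true_flux_umol Named list, area label -> c(CO2 =, CH4 =) true
#'   areal fluxes, umol m^-2 h^-1.
#' @param r_hourly True community respiration, mmol O2 m^-2 h^-1
#'   (negative: oxygen consumption).
#' @param p_hourly True light-period gross oxygen production,
#'   mmol O2 m^-2 h^-1 (positive).
#' @param gas_noise_sd Additive i.i.d. Gaussian noise on headspace
#'   concentrations, ppmv.
#' @param do_noise_sd Additive Gaussian noise on DO samples, mg L^-1.
#' @param detection_limit_ch4 GC detection limit for CH4, ppmv; samples
#'   at or below it are reported as non-detects.
#' @param sample_times_h Sampling schedule, h since closure, starting
#'   at 0.
#' @param dark_until_h Hours of darkness from closure; light afterwards.
#' @param geometry A [chamber_geometry()].
#' @param water_volume_L Enclosed water volume, L.
#' @param photoperiod_h Sunlight hours on the sampling day.
#' @param c0_ppmv Ambient headspace concentrations at closure,
#'   c(CO2 =, CH4 =), ppmv.
#' @param do0_mg_L DO at closure, mg L^-1.
#' @param temperature_range_C Diel temperature extremes, C (sinusoid).
#' @param patch_area_ha Named vector, area label -> patch area, ha.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_chambers_per_area = 3L,
    areas = c(bare_sand = "bare", E_acoroides = "vegetated",
              T_hemprichii = "vegetated"),
    true_flux_umol = list(
      bare_sand = c(CO2 = 0.0082, CH4 = 0),
      E_acoroides = c(CO2 = 0.143, CH4 = 0.130),
      T_hemprichii = c(CO2 = 0.0489, CH4 = 0.084)),
    r_hourly = -0.14,
    p_hourly = 0.35,
    gas_noise_sd = 0.5,
    do_noise_sd = 0.05,
    detection_limit_ch4 = 3,
    sample_times_h = c(0, 12, 18),
    dark_until_h = 12,
    geometry = chamber_geometry(area_m2 = 0.0707, headspace_volume_L = 1,
                                chamber_length_cm = 120,
                                insertion_depth_cm = 15),
    water_volume_L = 50,
    photoperiod_h = 12,
    c0_ppmv = c(CO2 = 420, CH4 = 2),
    do0_mg_L = 7,
    temperature_range_C = c(24.2, 33.6),
    patch_area_ha = c(bare_sand = 1, E_acoroides = 0.15,
                      T_hemprichii = 0.10)) {
  stopifnot(gas_noise_sd >= 0, do_noise_sd >= 0, detection_limit_ch4 >= 0,
            n_chambers_per_area >= 0, inherits(geometry, "chamber_geometry"))
  if (sample_times_h[1L] != 0 ||
      (length(sample_times_h) > 1L && any(diff(sample_times_h) <= 0)))
    stop("simulation_config: sample_times_h must start at 0 and increase",
         call. = FALSE)
  if (!all(names(true_flux_umol) %in% names(areas)))
    stop("simulation_config: true_flux_umol names must match areas",
         call. = FALSE)
  structure(list(seed = as.integer(seed),
                 n_chambers_per_area = as.integer(n_chambers_per_area),
                 areas = areas, true_flux_umol = true_flux_umol,
                 r_hourly = r_hourly, p_hourly = p_hourly,
                 gas_noise_sd = gas_noise_sd, do_noise_sd = do_noise_sd,
                 detection_limit_ch4 = detection_limit_ch4,
                 sample_times_h = sample_times_h,
                 dark_until_h = dark_until_h,
                 geometry = geometry, water_volume_L = water_volume_L,
                 photoperiod_h = photoperiod_h, c0_ppmv = c0_ppmv,
                 do0_mg_L = do0_mg_L,
                 temperature_range_C = temperature_range_C,
                 patch_area_ha = patch_area_ha),
            class = "simulation_config")
}

# diel sinusoid between the configured extremes, warmest mid-afternoon
simulate_temperature <- function(config, times_h = seq(0, 24, by = 1)) {
  lo <- config$temperature_range_C[1L]
  hi <- config$temperature_range_C[2L]
  mid <- (lo + hi) / 2
  amp <- (hi - lo) / 2
  # closure at dusk: coolest near dawn (t ~ 12 h), warmest near t ~ 0/24
  data.frame(time_h = times_h,
             temp_C = mid + amp * cos(2 * pi * times_h / 24))
}

# deterministic per-stream sub-seed (kept far below .Machine$integer.max)
stream_seed <- function(seed, area_label, suffix) {
  h <- sum(utf8ToInt(paste(area_label, suffix, sep = "/")) *
             seq_along(utf8ToInt(paste(area_label, suffix, sep = "/"))))
  (as.integer(seed) * 1000L + h %% 1000L) %% 2147483L
}

#' Simulate one headspace gas series
#'
#' Inverts the chamber flux equation generatively: the true areal flux
#' is converted to a concentration slope
#' `slope = F * A / (P V / (R T))` (ppmv h^-1) and samples are drawn as
#' `C(t) = C0 + slope * t + N(0, gas_noise_sd)`. CH4 samples at or below
#' the detection limit are reported as non-detects (the GC cannot
#' quantify them); CO2 is always well above its limit. Reproducible:
#' the same `(seed, area, gas)` triple always yields the same series.
#'
#' @param config A [simulation_config()].
#' @param area_label Name of an area in `config$areas`.
#' @param gas `"CO2"` or `"CH4"`.
#' @param chamber Replicate index (decorrelates noise across chambers).
#' @param temperature_series Optional precomputed temperature log.
#' @param constants A [flux_constants()].
#' @return A [gas_series()].
#' @export
simulate_gas_series <- function(config, area_label, gas, chamber = 1L,
                                temperature_series = NULL,
                                constants = flux_constants()) {
  gas <- match.arg(gas, c("CO2", "CH4"))
  if (is.null(temperature_series))
    temperature_series <- simulate_temperature(config)
  true_flux <- config$true_flux_umol[[area_label]][[gas]]
  T_K <- mean_kelvin(temperature_series, range(config$sample_times_h))
  n_air <- constants$P_atm * (config$geometry$headspace_volume_L / 1000) /
    (constants$R_gas * T_K)
  slope <- true_flux * config$geometry$area_m2 / n_air
  set.seed(stream_seed(config$seed, area_label,
                       paste0(gas, "#", chamber)))
  tt <- config$sample_times_h
  conc <- config$c0_ppmv[[gas]] + slope * tt +
    stats::rnorm(length(tt), 0, config$gas_noise_sd)
  conc <- pmax(conc, 0)
  detected <- if (gas == "CH4") conc > config$detection_limit_ch4
              else rep(TRUE, length(tt))
  conc[!detected] <- NA_real_
  gas_series(gas, tt, conc, detected = detected)
}

#' Simulate one dissolved-oxygen series
#'
#' DO declines during the dark hours at the rate implied by the true
#' respiration `r_hourly` and changes during light hours at the net rate
#' implied by `p_hourly + r_hourly` (production minus respiration),
#' inverting the areal-rate scaling used by [hourly_rate()]:
#' `dDO/dt = rate * 32 * A / V_water` (mg L^-1 h^-1). Gaussian noise is
#' added and DO is floored at 0. Reproducible given the seed.
#'
#' @inheritParams simulate_gas_series
#' @return A [do_series()].
#' @export
simulate_do_series <- function(config, area_label, chamber = 1L,
                               constants = flux_constants()) {
  conv <- constants$O2_molar_mass * config$geometry$area_m2 /
    config$water_volume_L        # (mg L-1 h-1) per (mmol O2 m-2 h-1)
  rate_mgL <- function(t)        # instantaneous DO slope at time t
    if (t < config$dark_until_h) config$r_hourly * conv
    else (config$p_hourly + config$r_hourly) * conv
  tt <- config$sample_times_h
  do_true <- numeric(length(tt))
  do_true[1L] <- config$do0_mg_L
  for (i in seq_along(tt)[-1L]) {
    # integrate piecewise-constant slope across the dark/light switch
    t0 <- tt[i - 1L]; t1 <- tt[i]
    brk <- min(max(config$dark_until_h, t0), t1)
    do_true[i] <- do_true[i - 1L] +
      rate_mgL(t0) * (brk - t0) + rate_mgL(brk) * (t1 - brk)
  }
  set.seed(stream_seed(config$seed, area_label, paste0("DO#", chamber)))
  noise <- stats::rnorm(length(tt), 0, config$do_noise_sd)
  do_series(tt, pmax(do_true + noise, 0))
}

#' Simulate a full multi-area chamber study
#'
#' Generates `n_chambers_per_area` deployments for every configured
#' area, each with CO2 and CH4 headspace series, a DO series and the
#' shared temperature log, as a list of [chamber_deployment()] ready for
#' the flux / metabolism / stats pipeline. The whole study is a
#' deterministic function of `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param constants A [flux_constants()].
#' @return Named list of [chamber_deployment()].
#' @export
simulate_study <- function(config, constants = flux_constants()) {
  stopifnot(inherits(config, "simulation_config"))
  temp <- simulate_temperature(config)
  out <- list()
  for (area in names(config$areas)) {
    for (ch in seq_len(config$n_chambers_per_area)) {
      id <- sprintf("%s_%d", area, ch)
      gases <- list(
        CO2 = simulate_gas_series(config, area, "CO2", ch, temp, constants),
        CH4 = simulate_gas_series(config, area, "CH4", ch, temp, constants))
      out[[id]] <- chamber_deployment(
        chamber_id = id,
        area_type = config$areas[[area]],
        species_label = if (config$areas[[area]] == "vegetated") area
                        else "",
        geometry = config$geometry,
        photoperiod_h = config$photoperiod_h,
        temperature_series = temp,
        gas_series = gases,
        do_series = simulate_do_series(config, area, ch, constants),
        water_volume_L = config$water_volume_L,
        patch_area_ha = unname(config$patch_area_ha[area]))
    }
  }
  out
}

#' Write a simulated study in the deployments CSV dialect
#'
#' Serialises deployments to `deployments.csv` (see [deployments-csv]),
#' the shared temperature log to `temperature.csv`, and -- when a
#' `config` is given -- the ground-truth parameters to `truth.csv` for
#' test harnesses.
#'
#' @param deployments List of [chamber_deployment()].
#' @param dir Output directory (created if needed).
#' @param config Optional [simulation_config()] for `truth.csv`.
#' @return Invisibly, the paths written.
#' @export
write_study <- function(deployments, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (d in deployments) {
    for (g in names(d$gas_series)) {
      s <- d$gas_series[[g]]
      do_at <- function(lab) {
        if (is.null(d$do_series)) return(NA_real_)
        i <- match(lab, d$do_series$label)
        if (is.na(i)) NA_real_ else d$do_series$do_mg_L[i]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chamber_id = d$chamber_id, area_type = d$area_type,
        species_label = d$species_label,
        patch_area_ha = d$patch_area_ha,
        area_m2 = d$geometry$area_m2,
        headspace_volume_L = d$geometry$headspace_volume_L,
        chamber_length_cm = d$geometry$chamber_length_cm,
        insertion_depth_cm = d$geometry$insertion_depth_cm,
        photoperiod_h = d$photoperiod_h,
        water_volume_L = d$water_volume_L,
        sample_label = s$label, time_h = s$time_h,
        gas = g,
        conc_ppmv = ifelse(s$detected, sprintf("%.10g", s$conc_ppmv),
                           "ND"),
        do_mg_per_L = vapply(s$label, do_at, 1),
        stringsAsFactors = FALSE)
    }
  }
  dep_path <- file.path(dir, "deployments.csv")
  utils::write.csv(do.call(rbind, rows), dep_path, row.names = FALSE,
                   quote = FALSE, na = "")
  temp_path <- file.path(dir, "temperature.csv")
  ts <- deployments[[1L]]$temperature_series
  utils::write.csv(data.frame(timestamp = ts$time_h, temp_C = ts$temp_C),
                   temp_path, row.names = FALSE, quote = FALSE)
  paths <- c(dep_path, temp_path)
  if (!is.null(config)) {
    truth <- do.call(rbind, lapply(names(config$true_flux_umol),
      function(a) data.frame(
        area = a,
        true_co2_umol_m2_h = config$true_flux_umol[[a]][["CO2"]],
        true_ch4_umol_m2_h = config$true_flux_umol[[a]][["CH4"]],
        r_hourly = config$r_hourly, p_hourly = config$p_hourly,
        stringsAsFactors = FALSE)))
    truth_path <- file.path(dir, "truth.csv")
    utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
    paths <- c(paths, truth_path)
  }
  invisible(paths)
}
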