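#' Chamber geometry
#'
#' Physical dimensions of a benthic chamber: the cross-sectional (basal)
#' area sealed onto the sediment, the volume of the gas headspace (the
#' trapped air pocket sampled for CO2/CH4), and the tube length and
#' sediment insertion depth. The headspace volume is a measured input --
#' it cannot be inferred from the tube length because the air pocket
#' depends on deployment conditions.
#'
#' @param area_m2 Cross-sectional area of the chamber base, m^2.
#' @param headspace_volume_L Gas headspace (air pocket) volume, L.
#' @param chamber_length_cm Total chamber length, cm (optional, NA allowed).
#' @param insertion_depth_cm Depth driven into the sediment, cm.
#' @return An object of class `chamber_geometry`.
#' @examples
#' chamber_geometry(area_m2 = 0.0707, headspace_volume_L = 5)
#' @export
chamber_geometry <- function(area_m2, headspace_volume_L,
                             chamber_length_cm = NA_real_,
                             insertion_depth_cm = NA_real_) {
  if (!is.finite(area_m2) || area_m2 <= 0)
    stop("chamber_geometry: area_m2 must be > 0", call. = FALSE)
  if (!is.finite(headspace_volume_L) || headspace_volume_L <= 0)
    stop("chamber_geometry: headspace_volume_L must be > 0", call. = FALSE)
  if (is.finite(chamber_length_cm) && is.finite(insertion_depth_cm) &&
      insertion_depth_cm >= chamber_length_cm)
    stop("chamber_geometry: insertion_depth_cm must be < chamber_length_cm",
         call. = FALSE)
  structure(list(area_m2 = area_m2,
                 headspace_volume_L = headspace_volume_L,
                 chamber_length_cm = chamber_length_cm,
                 insertion_depth_cm = insertion_depth_cm),
            class = "chamber_geometry")
}

#' Headspace gas concentration series
#'
#' Timestamped headspace concentrations of one gas in one chamber. Times
#' are decimal hours since chamber closure (the first sample, drawn ~10 min
#' after set-up, defines t = 0); the labels (`"t0"`, `"t1"`, ...) are
#' metadata used for interval-wise reporting. Samples below the analytical
#' detection limit carry `detected = FALSE` and an `NA` concentration --
#' a non-detect is never imputed as zero.
#'
#' @param gas `"CO2"` or `"CH4"`.
#' @param time_h Numeric vector, hours since closure, strictly increasing.
#' @param conc_ppmv Concentrations, ppmv; `NA` where not detected.
#' @param detected Logical vector; defaults to `!is.na(conc_ppmv)`.
#' @param label Character sample labels; defaults to `t0, t1, ...`.
#' @return An object of class `gas_series` (a data.frame).
#' @export
gas_series <- function(gas, time_h, conc_ppmv,
                       detected = !is.na(conc_ppmv),
                       label = paste0("t", seq_along(time_h) - 1L)) {
  gas <- match.arg(gas, c("CO2", "CH4"))
  n <- length(time_h)
  if (length(conc_ppmv) != n || length(detected) != n || length(label) != n)
    stop("gas_series: time_h, conc_ppmv, detected, label lengths differ",
         call. = FALSE)
  if (n > 1 && any(diff(time_h) <= 0))
    stop("gas_series: time_h must be strictly increasing", call. = FALSE)
  if (any(detected & (is.na(conc_ppmv) | conc_ppmv < 0)))
    stop("gas_series: detected samples need concentrations >= 0",
         call. = FALSE)
  conc_ppmv[!detected] <- NA_real_
  structure(data.frame(label = as.character(label), time_h = time_h,
                       conc_ppmv = conc_ppmv, detected = detected,
                       stringsAsFactors = FALSE),
            gas = gas, class = c("gas_series", "data.frame"))
}

#' Dissolved-oxygen series
#'
#' Timestamped dissolved-oxygen concentrations (mg O2 L^-1) in the chamber
#' water phase, on the same time axis as [gas_series()].
#'
#' @param time_h Hours since closure, strictly increasing.
#' @param do_mg_L DO concentrations, mg O2 L^-1, all >= 0.
#' @param label Character sample labels; defaults to `t0, t1, ...`.
#' @return An object of class `do_series` (a data.frame).
#' @export
do_series <- function(time_h, do_mg_L,
                      label = paste0("t", seq_along(time_h) - 1L)) {
  n <- length(time_h)
  if (length(do_mg_L) != n || length(label) != n)
    stop("do_series: vector lengths differ", call. = FALSE)
  if (n > 1 && any(diff(time_h) <= 0))
    stop("do_series: time_h must be strictly increasing", call. = FALSE)
  if (any(!is.na(do_mg_L) & do_mg_L < 0))
    stop("do_series: DO must be >= 0", call. = FALSE)
  structure(data.frame(label = as.character(label), time_h = time_h,
                       do_mg_L = do_mg_L, stringsAsFactors = FALSE),
            class = c("do_series", "data.frame"))
}

#' One chamber deployment
#'
#' Everything recorded for a single chamber: identity and area-type
#' metadata, geometry, photoperiod on the sampling day, the in-chamber
#' temperature log, headspace gas series and the water-phase DO series.
#' The water volume enclosed by the chamber is distinct from the gas
#' headspace volume: gas fluxes use the air pocket, metabolism uses the
#' water phase.
#'
#' @param chamber_id Character id, unique within a study.
#' @param area_type `"vegetated"` or `"bare"`.
#' @param species_label Free-text species name; `""` for bare sediment.
#' @param geometry A [chamber_geometry()].
#' @param photoperiod_h Sunlight hours on the sampling day, in (0, 24].
#' @param temperature_series data.frame with columns `time_h`, `temp_C`.
#' @param gas_series Named list of [gas_series()] objects (names = gas).
#' @param do_series A [do_series()] or `NULL`.
#' @param water_volume_L Enclosed water volume, L (needed for metabolism).
#' @param patch_area_ha Patch area of this area type, ha (optional).
#' @return An object of class `chamber_deployment`.
#' @export
chamber_deployment <- function(chamber_id, area_type, geometry,
                               species_label = "",
                               photoperiod_h = 12,
                               temperature_series = NULL,
                               gas_series = list(),
                               do_series = NULL,
                               water_volume_L = NA_real_,
                               patch_area_ha = NA_real_) {
  area_type <- match.arg(area_type, c("vegetated", "bare"))
  stopifnot(inherits(geometry, "chamber_geometry"))
  if (!is.finite(photoperiod_h) || photoperiod_h <= 0 || photoperiod_h > 24)
    stop("chamber_deployment: photoperiod_h must be in (0, 24]",
         call. = FALSE)
  if (!is.null(temperature_series)) {
    if (!all(c("time_h", "temp_C") %in% names(temperature_series)))
      stop("temperature_series needs columns time_h, temp_C", call. = FALSE)
  }
  structure(list(chamber_id = as.character(chamber_id),
                 area_type = area_type,
                 species_label = species_label,
                 geometry = geometry,
                 photoperiod_h = photoperiod_h,
                 temperature_series = temperature_series,
                 gas_series = gas_series,
                 do_series = do_series,
                 water_volume_L = water_volume_L,
                 patch_area_ha = patch_area_ha),
            class = "chamber_deployment")
}

#' @export
print.chamber_deployment <- function(x, ...) {
  cat(sprintf("<chamber_deployment> %s (%s%s)\n", x$chamber_id, x$area_type,
              if (nzchar(x$species_label)) paste0(": ", x$species_label)
              else ""))
  cat(sprintf("  gases: %s | DO samples: %d | temperature readings: %d\n",
              paste(names(x$gas_series), collapse = ", "),
              if (is.null(x$do_series)) 0L else nrow(x$do_series),
              if (is.null(x$temperature_series)) 0L
              else nrow(x$temperature_series)))
  invisible(x)
}
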