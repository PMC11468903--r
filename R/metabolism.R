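#' Hourly areal oxygen exchange rate from two DO samples
#'
#' The building block of chamber metabolism: the DO change between two
#' water samples, scaled to an areal molar rate,
#' \deqn{rate = \frac{DO_{end} - DO_{start}}{\Delta t}
#'   \times \frac{V_{water}}{A} \times \frac{1}{32}}
#' with DO in mg O2 L^-1, elapsed time in h, water volume in L, area in
#' m^2 and 32 g mol^-1 the molar mass of O2, giving mmol O2 m^-2 h^-1.
#' The sign is preserved: a DO decline (dark-period respiration) gives a
#' negative rate.
#'
#' @param do_start,do_end DO concentrations, mg O2 L^-1.
#' @param dt_h Elapsed time between the samples, h (> 0).
#' @param water_volume_L Enclosed water volume, L.
#' @param area_m2 Chamber basal area, m^2.
#' @param constants A [flux_constants()] (supplies the O2 molar mass).
#' @return Rate in mmol O2 m^-2 h^-1.
#' @export
hourly_rate <- function(do_start, do_end, dt_h, water_volume_L, area_m2,
                        constants = flux_constants()) {
  if (!is.finite(dt_h) || dt_h <= 0)
    stop("hourly_rate: dt_h must be > 0", call. = FALSE)
  if (!is.finite(water_volume_L) || water_volume_L <= 0 ||
      !is.finite(area_m2) || area_m2 <= 0)
    stop("hourly_rate: volume and area must be > 0", call. = FALSE)
  (do_end - do_start) / dt_h * (water_volume_L / area_m2) /
    constants$O2_molar_mass
}

#' Hourly community metabolism from a three-sample DO series
#'
#' Community respiration (CR) is the DO rate over the dark interval
#' (t0 -> t1, evening to dawn) and net community production (NCP) the DO
#' rate over the light interval (t1 -> t2, dawn to midday); gross primary
#' production follows the identity GPP = CR + NCP. CR is carried with its
#' natural negative sign (oxygen consumption), so the identity and the
#' daily budget below are plain arithmetic with signed quantities.
#'
#' The default interval-to-process mapping (dark first, then light)
#' matches an evening deployment sampled at dusk, dawn and noon; pass
#' `dark` / `light` label pairs to fit other schedules.
#'
#' @param do A [do_series()] containing the labeled samples.
#' @param water_volume_L Enclosed water volume, L.
#' @param area_m2 Chamber basal area, m^2.
#' @param constants A [flux_constants()].
#' @param dark,light Length-2 character vectors naming the (start, end)
#'   sample labels of the dark and light intervals.
#' @return List with `cr_hourly`, `ncp_hourly`, `gpp_hourly`
#'   (mmol O2 m^-2 h^-1; numerically mmol C with PQ = RQ = 1).
#' @export
hourly_metabolism <- function(do, water_volume_L, area_m2,
                              constants = flux_constants(),
                              dark = c("t0", "t1"),
                              light = c("t1", "t2")) {
  stopifnot(inherits(do, "do_series"))
  need <- unique(c(dark, light))
  missing <- setdiff(need, do$label)
  if (length(missing))
    stop("hourly_metabolism: DO series lacks sample label(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  at <- function(lab) {
    row <- do[match(lab, do$label), ]
    list(t = row$time_h, y = row$do_mg_L)
  }
  rate <- function(pair) {
    a <- at(pair[1L]); b <- at(pair[2L])
    hourly_rate(a$y, b$y, b$t - a$t, water_volume_L, area_m2, constants)
  }
  cr <- rate(dark)
  ncp <- rate(light)
  list(cr_hourly = cr, ncp_hourly = ncp, gpp_hourly = cr + ncp)
}

#' Daily metabolism and trophic status from hourly rates
#'
#' Scales hourly rates to daily budgets: GPP runs only during daylight
#' (`gpp_daily = gpp_hourly * photoperiod`), respiration around the clock
#' (`cr_daily = cr_hourly * 24`), and the daily net balance is
#' `ncp_daily = gpp_daily - cr_daily` (with CR negative this adds back
#' the respired amount). O2 rates are relabeled as carbon rates because
#' the photosynthetic and respiratory quotients both default to 1; other
#' quotients rescale GPP by PQ and CR by RQ.
#'
#' @param hourly List with `cr_hourly`, `ncp_hourly`, `gpp_hourly` as
#'   returned by [hourly_metabolism()].
#' @param photoperiod_h Sunlight hours on the sampling day, in (0, 24].
#' @param constants A [flux_constants()].
#' @param threshold Trophic classification threshold passed to
#'   [classify_trophic()].
#' @return An object of class `metabolism_result`: hourly and daily CR /
#'   NCP / GPP in mmol C m^-2 (h^-1 or d^-1) plus `trophic_status`.
#' @export
daily_metabolism <- function(hourly, photoperiod_h,
                             constants = flux_constants(),
                             threshold = 0) {
  if (!is.finite(photoperiod_h) || photoperiod_h <= 0 || photoperiod_h > 24)
    stop("daily_metabolism: photoperiod_h must be in (0, 24]",
         call. = FALSE)
  # O2 -> C conversion; identity at the default PQ = RQ = 1
  gpp_h <- hourly$gpp_hourly * constants$PQ
  cr_h <- hourly$cr_hourly * constants$RQ
  ncp_h <- hourly$ncp_hourly
  gpp_d <- gpp_h * photoperiod_h
  cr_d <- cr_h * 24
  ncp_d <- gpp_d - cr_d
  structure(list(cr_hourly = cr_h, ncp_hourly = ncp_h, gpp_hourly = gpp_h,
                 gpp_daily = gpp_d, cr_daily = cr_d, ncp_daily = ncp_d,
                 trophic_status = classify_trophic(ncp_d, threshold)),
            class = "metabolism_result")
}

#' @export
print.metabolism_result <- function(x, ...) {
  cat("<metabolism_result> (mmol C m-2)\n")
  cat(sprintf("  hourly: CR %.4g  NCP %.4g  GPP %.4g\n",
              x$cr_hourly, x$ncp_hourly, x$gpp_hourly))
  cat(sprintf("  daily : CR %.4g  NCP %.4g  GPP %.4g  [%s]\n",
              x$cr_daily, x$ncp_daily, x$gpp_daily, x$trophic_status))
  invisible(x)
}

#' Classify trophic status from daily net community production
#'
#' A community fixing more carbon than it respires (NCP above the
#' threshold) is autotrophic; one respiring more than it fixes (NCP below
#' minus the threshold) is heterotrophic; anything between is balanced.
#' The default threshold 0 is the standard metabolic-balance boundary;
#' some studies use a stricter cut (e.g. NCP > 1 mmol C m^-2 d^-1), which
#' is available by setting `threshold`.
#'
#' @param ncp_daily Daily NCP, mmol C m^-2 d^-1.
#' @param threshold Non-negative classification margin, same units.
#' @return `"autotrophic"`, `"heterotrophic"` or `"balanced"`.
#' @export
classify_trophic <- function(ncp_daily, threshold = 0) {
  if (!is.finite(threshold) || threshold < 0)
    stop("classify_trophic: threshold must be >= 0", call. = FALSE)
  if (ncp_daily > threshold) "autotrophic"
  else if (ncp_daily < -threshold) "heterotrophic"
  else "balanced"
}

#' Full metabolism result for one deployment
#'
#' Runs [hourly_metabolism()] and [daily_metabolism()] on a deployment's
#' DO series using its geometry, water volume and photoperiod.
#'
#' @param deployment A [chamber_deployment()] with a DO series and a
#'   finite `water_volume_L`.
#' @param constants A [flux_constants()].
#' @param threshold Trophic threshold, mmol C m^-2 d^-1.
#' @return A `metabolism_result`.
#' @export
deployment_metabolism <- function(deployment, constants = flux_constants(),
                                  threshold = 0) {
  stopifnot(inherits(deployment, "chamber_deployment"))
  if (is.null(deployment$do_series))
    stop("deployment_metabolism: no DO series on chamber ",
         deployment$chamber_id, call. = FALSE)
  if (!is.finite(deployment$water_volume_L))
    stop("deployment_metabolism: water_volume_L missing for chamber ",
         deployment$chamber_id, call. = FALSE)
  h <- hourly_metabolism(deployment$do_series, deployment$water_volume_L,
                         deployment$geometry$area_m2, constants)
  daily_metabolism(h, deployment$photoperiod_h, constants, threshold)
}
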