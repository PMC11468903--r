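#' Ordinary least-squares slope of concentration on time
#'
#' Fits concentration ~ time by OLS and returns the slope (ppmv h^-1),
#' the coefficient of determination and the number of points used. With
#' exactly two points the slope is the difference quotient and r^2 = 1.
#' The intercept (ambient concentration at closure) is discarded.
#'
#' @param time_h Sampling times, h.
#' @param conc_ppmv Concentrations, ppmv.
#' @return List with `slope_ppmv_h`, `r_squared`, `n_points`.
#' @export
fit_slope <- function(time_h, conc_ppmv) {
  keep <- is.finite(time_h) & is.finite(conc_ppmv)
  t <- time_h[keep]; y <- conc_ppmv[keep]
  n <- length(t)
  if (n < 2L || length(unique(t)) < 2L)
    stop("fit_slope: need >= 2 points with distinct times", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, t), y)
  slope <- unname(fit$coefficients[2L])
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(fit$residuals^2) / sst
  list(slope_ppmv_h = slope, r_squared = r2, n_points = n)
}

#' Mean chamber temperature in Kelvin over a time window
#'
#' Arithmetic mean of the logger readings falling inside `window`
#' (inclusive), converted to Kelvin. If no reading falls inside the window
#' the single reading nearest to the window midpoint is used.
#'
#' @param temperature_series data.frame with `time_h` and `temp_C`.
#' @param window Numeric length-2 vector `(start_h, end_h)`; `NULL` uses
#'   the full series.
#' @return Mean temperature, K.
#' @export
mean_kelvin <- function(temperature_series, window = NULL) {
  if (is.null(temperature_series) || nrow(temperature_series) == 0L)
    stop("mean_kelvin: empty temperature series", call. = FALSE)
  tt <- temperature_series$time_h
  tc <- temperature_series$temp_C
  if (!is.null(window)) {
    inside <- tt >= window[1L] & tt <= window[2L]
    if (any(inside)) {
      tc <- tc[inside]
    } else {
      mid <- mean(window)
      tc <- tc[which.min(abs(tt - mid))]
    }
  }
  mean(tc) + 273.15
}

flux_result <- function(gas, slope = NA_real_, r_squared = NA_real_,
                        n_points = 0L, mean_temperature_K = NA_real_,
                        flux_umol_m2_h = NA_real_, flux_ug_m2_h = NA_real_,
                        status = "ok", interval = "all") {
  structure(list(gas = gas, interval = interval,
                 slope_ppmv_h = slope, r_squared = r_squared,
                 n_points = n_points,
                 mean_temperature_K = mean_temperature_K,
                 flux_umol_m2_h = flux_umol_m2_h,
                 flux_ug_m2_h = flux_ug_m2_h,
                 status = status),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf("<flux_result> %s [%s] status=%s\n", x$gas, x$interval,
              x$status))
  if (x$status == "ok")
    cat(sprintf("  slope %.4g ppmv/h (r2=%.4f, n=%d, T=%.2f K) -> %.4g umol m-2 h-1\n",
                x$slope_ppmv_h, x$r_squared, x$n_points,
                x$mean_temperature_K, x$flux_umol_m2_h))
  invisible(x)
}

#' Areal gas flux from a chamber headspace series
#'
#' Converts the fitted concentration slope to an areal flux with the
#' ideal gas law:
#' \deqn{F = \frac{dG}{dt} \times \frac{P V}{R T A}}
#' where dG/dt is in ppmv h^-1, V is the headspace volume (m^3), P the
#' barometric pressure (atm), R the ideal gas constant
#' (8.205746e-5 atm m^3 K^-1 mol^-1), T the mean in-chamber temperature
#' (K) over the fitted span, and A the basal area (m^2). Because ppmv is
#' micromol of gas per mol of headspace air, PV/(RT) is the total moles of
#' headspace air and F comes out in umol m^-2 h^-1. For CH4 the flux is
#' additionally expressed in ug m^-2 h^-1 via its molar mass. Negative
#' slopes yield negative fluxes (net uptake) -- they are never clipped.
#'
#' Series with fewer than two detected samples are returned with status
#' `"nondetect"` (no sample detected) or `"insufficient_points"` rather
#' than raising an error, so pipeline runs survive damaged chambers.
#'
#' @param series A [gas_series()].
#' @param geometry A [chamber_geometry()].
#' @param temperature_series data.frame with `time_h`, `temp_C`.
#' @param constants A [flux_constants()].
#' @param window Temperature-averaging window; default spans the detected
#'   samples used in the fit.
#' @param interval Label stored on the result (`"all"` for the whole
#'   series fit).
#' @return A `flux_result`.
#' @export
compute_flux <- function(series, geometry, temperature_series,
                         constants = flux_constants(), window = NULL,
                         interval = "all") {
  stopifnot(inherits(series, "gas_series"),
            inherits(geometry, "chamber_geometry"))
  gas <- attr(series, "gas")
  det <- series[series$detected, , drop = FALSE]
  if (nrow(det) == 0L)
    return(flux_result(gas, status = "nondetect", interval = interval))
  if (nrow(det) < 2L)
    return(flux_result(gas, n_points = nrow(det),
                       status = "insufficient_points", interval = interval))
  fit <- fit_slope(det$time_h, det$conc_ppmv)
  if (is.null(window)) window <- range(det$time_h)
  T_K <- mean_kelvin(temperature_series, window)
  # total moles of headspace air; ppmv == umol gas per mol air
  n_air <- constants$P_atm * (geometry$headspace_volume_L / 1000) /
    (constants$R_gas * T_K)
  flux_umol <- fit$slope_ppmv_h * n_air / geometry$area_m2
  flux_ug <- if (gas == "CH4") flux_umol * constants$CH4_molar_mass
             else NA_real_
  flux_result(gas, slope = fit$slope_ppmv_h, r_squared = fit$r_squared,
              n_points = fit$n_points, mean_temperature_K = T_K,
              flux_umol_m2_h = flux_umol, flux_ug_m2_h = flux_ug,
              status = "ok", interval = interval)
}

#' Per-interval fluxes between consecutive labeled samples
#'
#' Computes one two-point flux per consecutive sample pair (t0->t1,
#' t1->t2, ...), enabling comparisons across sampling times. An interval
#' with a missing (non-detected) endpoint is reported with status
#' `"insufficient_points"` rather than silently dropped, so damaged
#' chambers leave a visible skip record. Each interval uses its own
#' temperature window.
#'
#' @inheritParams compute_flux
#' @return List of `flux_result`, one per interval.
#' @export
flux_by_interval <- function(series, geometry, temperature_series,
                             constants = flux_constants()) {
  stopifnot(inherits(series, "gas_series"))
  n <- nrow(series)
  if (n < 2L) return(list())
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    pair <- series[c(i, i + 1L), , drop = FALSE]
    lab <- paste0(pair$label[1L], "-", pair$label[2L])
    sub <- gas_series(attr(series, "gas"), pair$time_h, pair$conc_ppmv,
                      detected = pair$detected, label = pair$label)
    out[[i]] <- compute_flux(sub, geometry, temperature_series, constants,
                             window = range(pair$time_h), interval = lab)
  }
  out
}

#' Whole-series and per-interval fluxes for every gas of a deployment
#'
#' Convenience wrapper running [compute_flux()] (whole-series OLS over all
#' detected samples) and [flux_by_interval()] for each gas series attached
#' to a deployment, returned as a tidy data.frame.
#'
#' @param deployment A [chamber_deployment()].
#' @param constants A [flux_constants()].
#' @param intervals Also compute per-interval two-point fluxes?
#' @return data.frame with one row per chamber x gas x interval.
#' @export
deployment_fluxes <- function(deployment, constants = flux_constants(),
                              intervals = TRUE) {
  stopifnot(inherits(deployment, "chamber_deployment"))
  rows <- list()
  for (g in names(deployment$gas_series)) {
    s <- deployment$gas_series[[g]]
    res <- list(compute_flux(s, deployment$geometry,
                             deployment$temperature_series, constants))
    if (intervals && nrow(s) > 2L) {
      res <- c(res, flux_by_interval(s, deployment$geometry,
                                     deployment$temperature_series,
                                     constants))
    }
    rows <- c(rows, lapply(res, function(r) {
      data.frame(chamber_id = deployment$chamber_id,
                 area_type = deployment$area_type,
                 species_label = deployment$species_label,
                 gas = r$gas, interval = r$interval,
                 slope_ppmv_h = r$slope_ppmv_h, r2 = r$r_squared,
                 n = r$n_points, T_K = r$mean_temperature_K,
                 flux_umol_m2_h = r$flux_umol_m2_h,
                 flux_ug_m2_h = r$flux_ug_m2_h, status = r$status,
                 stringsAsFactors = FALSE)
    }))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
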