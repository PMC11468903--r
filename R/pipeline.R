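#' Flux table for a whole study
#'
#' Runs [deployment_fluxes()] over a list of deployments and binds the
#' results into one tidy table (one row per chamber x gas x interval).
#'
#' @param deployments List of [chamber_deployment()].
#' @param constants A [flux_constants()].
#' @param intervals Also report per-interval two-point fluxes?
#' @return data.frame.
#' @export
study_fluxes <- function(deployments, constants = flux_constants(),
                         intervals = TRUE) {
  do.call(rbind, c(lapply(deployments, deployment_fluxes,
                          constants = constants, intervals = intervals),
                   list(make.row.names = FALSE)))
}

#' Metabolism table for a whole study
#'
#' Runs [deployment_metabolism()] over a list of deployments; chambers
#' without a usable DO series are skipped with a warning.
#'
#' @param deployments List of [chamber_deployment()].
#' @param constants A [flux_constants()].
#' @param threshold Trophic classification threshold, mmol C m^-2 d^-1.
#' @return data.frame, one row per chamber, units in column names.
#' @export
study_metabolism <- function(deployments, constants = flux_constants(),
                             threshold = 0) {
  rows <- lapply(deployments, function(d) {
    m <- tryCatch(deployment_metabolism(d, constants, threshold),
                  error = function(e) {
                    warning("skipping chamber ", d$chamber_id, ": ",
                            conditionMessage(e), call. = FALSE)
                    NULL
                  })
    if (is.null(m)) return(NULL)
    data.frame(chamber_id = d$chamber_id, area_type = d$area_type,
               species_label = d$species_label,
               cr_hourly_mmol_m2_h = m$cr_hourly,
               ncp_hourly_mmol_m2_h = m$ncp_hourly,
               gpp_hourly_mmol_m2_h = m$gpp_hourly,
               gpp_daily_mmol_m2_d = m$gpp_daily,
               cr_daily_mmol_m2_d = m$cr_daily,
               ncp_daily_mmol_m2_d = m$ncp_daily,
               trophic_status = m$trophic_status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows[!vapply(rows, is.null, TRUE)],
                   list(make.row.names = FALSE)))
}

#' Per-area mean fluxes with non-detects excluded
#'
#' Whole-series (`interval == "all"`) rows with status `"ok"` are
#' averaged by area and gas. Non-detect and insufficient-point chambers
#' are excluded from the mean -- never imputed as zero -- and counted in
#' `n_excluded`.
#'
#' @param flux_table data.frame from [study_fluxes()].
#' @param by Grouping column, default `"area_type"`; use
#'   `"species_label"` or `"chamber_id"` for finer groupings.
#' @return data.frame with mean and sd of the molar flux per group x gas.
#' @export
area_mean_fluxes <- function(flux_table, by = "area_type") {
  ft <- flux_table[flux_table$interval == "all", , drop = FALSE]
  key <- interaction(ft[[by]], ft$gas, drop = TRUE)
  rows <- lapply(split(ft, key), function(s) {
    ok <- s$status == "ok"
    data.frame(group = s[[by]][1L], gas = s$gas[1L],
               mean_flux_umol_m2_h = if (any(ok))
                 mean(s$flux_umol_m2_h[ok]) else NA_real_,
               sd_flux_umol_m2_h = if (sum(ok) > 1L)
                 stats::sd(s$flux_umol_m2_h[ok]) else NA_real_,
               n_used = sum(ok), n_excluded = sum(!ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  names(out)[1L] <- by
  out
}
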