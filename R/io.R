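#' @name deployments-csv
#' @title The deployments CSV dialect
#' @description
#' Field records are exchanged as a long-format, comma-delimited,
#' period-decimal CSV with one row per chamber x sample x gas:
#'
#' \preformatted{
#' chamber_id, area_type, species_label, patch_area_ha, area_m2,
#' headspace_volume_L, chamber_length_cm, insertion_depth_cm,
#' photoperiod_h, water_volume_L, sample_label, time_h, gas, conc_ppmv,
#' do_mg_per_L
#' }
#'
#' `time_h` is decimal hours since chamber closure (the first sample,
#' drawn shortly after set-up, is t = 0); labels like t0/t1/t2 are
#' metadata. A concentration below the detection limit is the literal
#' token `ND` in `conc_ppmv` -- never a zero. `do_mg_per_L` may repeat
#' across the gas rows of one sample event; the first non-missing value
#' per label wins. `water_volume_L` (the enclosed water phase used for
#' metabolism, distinct from the gas headspace) is optional; metabolism
#' requires it.
NULL

.deploy_cols <- c("chamber_id", "area_type", "species_label",
                  "patch_area_ha", "area_m2", "headspace_volume_L",
                  "chamber_length_cm", "insertion_depth_cm",
                  "photoperiod_h", "sample_label", "time_h", "gas",
                  "conc_ppmv", "do_mg_per_L")

#' Read chamber deployments from a long-format CSV
#'
#' Parses the dialect documented in [deployments-csv], groups rows by
#' chamber, sorts samples in time and builds one [chamber_deployment()]
#' per chamber. `ND` concentration tokens become non-detect gas samples
#' (`detected = FALSE`). Temperature logs are attached afterwards with
#' [attach_temperature()].
#'
#' @param path CSV file path.
#' @param constants A [flux_constants()] (kept for signature symmetry;
#'   the reader itself is unit-free).
#' @return Named list of [chamber_deployment()] (names = chamber ids).
#' @section Errors: a missing required column raises a schema error
#'   naming the column; non-monotone sample times within a chamber raise
#'   a validation error naming the chamber; unparseable numeric fields
#'   are reported with their line numbers.
#' @export
read_deployments <- function(path, constants = flux_constants()) {
  if (!file.exists(path))
    stop("read_deployments: no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", strip.white = TRUE)
  missing <- setdiff(.deploy_cols, names(df))
  if (length(missing))
    stop("read_deployments: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!"water_volume_L" %in% names(df)) df$water_volume_L <- NA
  if (nrow(df) == 0L) return(list())

  num <- function(col) {
    x <- df[[col]]
    x[x %in% c("", "NA")] <- NA
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad))
      stop("read_deployments: unparseable numeric '", col, "' on line(s) ",
           paste(bad + 1L, collapse = ", "), call. = FALSE)
    v
  }
  nd <- toupper(df$conc_ppmv) == "ND"
  df$conc_ppmv[nd] <- NA
  conc <- num("conc_ppmv")
  time_h <- num("time_h")
  do_mg <- num("do_mg_per_L")

  out <- list()
  for (id in unique(df$chamber_id)) {
    rows <- which(df$chamber_id == id)
    sub <- df[rows, ]
    geom <- chamber_geometry(
      area_m2 = num("area_m2")[rows][1L],
      headspace_volume_L = num("headspace_volume_L")[rows][1L],
      chamber_length_cm = num("chamber_length_cm")[rows][1L],
      insertion_depth_cm = num("insertion_depth_cm")[rows][1L])
    gases <- list()
    for (g in intersect(c("CO2", "CH4"), unique(sub$gas))) {
      sel <- sub$gas == g
      o <- order(time_h[rows][sel])
      tg <- time_h[rows][sel][o]
      if (any(diff(tg) <= 0))
        stop("read_deployments: non-monotone ", g,
             " sample times in chamber '", id, "'", call. = FALSE)
      gases[[g]] <- gas_series(g, tg, conc[rows][sel][o],
                               detected = !nd[rows][sel][o],
                               label = sub$sample_label[sel][o])
    }
    # one DO value per sample event: first non-missing across gas rows
    dos <- NULL
    has_do <- !is.na(do_mg[rows])
    if (any(has_do)) {
      labs <- unique(sub$sample_label[has_do])
      dt <- vapply(labs, function(l)
        time_h[rows][has_do & sub$sample_label == l][1L], 1)
      dv <- vapply(labs, function(l)
        do_mg[rows][has_do & sub$sample_label == l][1L], 1)
      o <- order(dt)
      if (any(diff(dt[o]) <= 0))
        stop("read_deployments: non-monotone DO sample times in chamber '",
             id, "'", call. = FALSE)
      dos <- do_series(dt[o], dv[o], label = labs[o])
    }
    out[[id]] <- chamber_deployment(
      chamber_id = id,
      area_type = sub$area_type[1L],
      species_label = sub$species_label[1L],
      geometry = geom,
      photoperiod_h = num("photoperiod_h")[rows][1L],
      gas_series = gases,
      do_series = dos,
      water_volume_L = num("water_volume_L")[rows][1L],
      patch_area_ha = num("patch_area_ha")[rows][1L])
  }
  out
}

#' Read a chamber temperature log
#'
#' Parses a minimal two-column logger export: `timestamp` (ISO-8601,
#' e.g. `2023-06-14T18:00:00`, or already-decimal hours) and `temp_C`.
#' Timestamps are converted to decimal hours relative to the first row
#' (deployment start); Celsius values are preserved. Vendor-specific
#' logger exports must be pre-converted to this dialect.
#'
#' @param path CSV file path.
#' @return data.frame with columns `time_h` and `temp_C`.
#' @section Errors: an unparseable timestamp is reported with its row
#'   number; out-of-order rows raise a validation error.
#' @export
read_temperature_log <- function(path) {
  if (!file.exists(path))
    stop("read_temperature_log: no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", strip.white = TRUE)
  missing <- setdiff(c("timestamp", "temp_C"), names(df))
  if (length(missing))
    stop("read_temperature_log: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L)
    return(data.frame(time_h = numeric(0), temp_C = numeric(0)))
  ts <- df$timestamp
  hours <- suppressWarnings(as.numeric(ts))
  if (any(is.na(hours))) {
    parsed <- strptime(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M",
                  "%Y-%m-%d %H:%M")) {
      miss <- is.na(parsed)
      if (!any(miss)) break
      parsed[miss] <- strptime(ts[miss], fmt, tz = "UTC")
    }
    bad <- which(is.na(parsed))
    if (length(bad))
      stop("read_temperature_log: unparseable timestamp on row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    hours <- as.numeric(difftime(parsed, parsed[1L], units = "hours"))
  }
  temp <- suppressWarnings(as.numeric(df$temp_C))
  bad <- which(is.na(temp))
  if (length(bad))
    stop("read_temperature_log: unparseable temp_C on row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (length(hours) > 1L && any(diff(hours) <= 0))
    stop("read_temperature_log: timestamps out of order", call. = FALSE)
  data.frame(time_h = hours, temp_C = temp)
}

#' Attach a shared temperature log to deployments
#'
#' @param deployments List of [chamber_deployment()].
#' @param temperature_series data.frame from [read_temperature_log()].
#' @return The deployments with `temperature_series` set.
#' @export
attach_temperature <- function(deployments, temperature_series) {
  lapply(deployments, function(d) {
    d$temperature_series <- temperature_series
    d
  })
}

#' Write a tidy results table to CSV
#'
#' Writes flux or metabolism result tables (as produced by
#' [deployment_fluxes()], [study_fluxes()] or [study_metabolism()]) with
#' a deterministic column order and enough digits (15 significant) that a
#' read-back reproduces every numeric field. Units are embedded in the
#' column names of those tables.
#'
#' @param results data.frame (possibly empty: a header-only file is
#'   written).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  num <- vapply(results, is.numeric, TRUE)
  out <- results
  out[num] <- lapply(results[num], function(v)
    ifelse(is.na(v), "", sprintf("%.15g", v)))
  tryCatch(utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                            na = ""),
           error = function(e)
             stop("write_results: cannot write '", path, "': ",
                  conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read back a results CSV written by [write_results()]
#'
#' @param path CSV path.
#' @return data.frame with numeric columns restored.
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df
}
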