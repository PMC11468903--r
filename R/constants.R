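#' Physical constants and conversion factors
#'
#' Bundles the constants used throughout the flux and metabolism
#' calculations. Defaults are the values standard in closed-chamber work:
#' the ideal gas constant in atm-based units, 1 atm barometric pressure,
#' molar masses of O2, CO2 and CH4, photosynthetic and respiratory
#' quotients of 1 (so O2-based metabolic rates are numerically equal to
#' carbon rates), and a sustained-flux global warming potential (SGWP)
#' multiplier for CH4. SGWP for a sustained CH4 flux is 45--96 times CO2
#' depending on time horizon; the conservative low end is the default.
#'
#' @param R_gas Ideal gas constant, atm m^3 K^-1 mol^-1.
#' @param P_atm Barometric pressure, atm.
#' @param O2_molar_mass Molar mass of O2, g mol^-1.
#' @param CO2_molar_mass Molar mass of CO2, g mol^-1.
#' @param CH4_molar_mass Molar mass of CH4, g mol^-1.
#' @param PQ Photosynthetic quotient, mol CO2 fixed per mol O2 evolved.
#' @param RQ Respiratory quotient, mol CO2 released per mol O2 consumed.
#' @param SGWP_CH4 Sustained-flux global warming potential of CH4 relative
#'   to CO2 (dimensionless); values outside [45, 96] trigger a warning.
#' @return An object of class `flux_constants` (a validated list).
#' @examples
#' cc <- flux_constants()
#' cc$R_gas
#' @export
flux_constants <- function(R_gas = 8.205746e-5,
                           P_atm = 1,
                           O2_molar_mass = 32,
                           CO2_molar_mass = 44.01,
                           CH4_molar_mass = 16.04,
                           PQ = 1,
                           RQ = 1,
                           SGWP_CH4 = 45) {
  x <- list(R_gas = R_gas, P_atm = P_atm,
            O2_molar_mass = O2_molar_mass,
            CO2_molar_mass = CO2_molar_mass,
            CH4_molar_mass = CH4_molar_mass,
            PQ = PQ, RQ = RQ, SGWP_CH4 = SGWP_CH4)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("flux_constants: '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  if (SGWP_CH4 < 45 || SGWP_CH4 > 96) {
    warning("SGWP_CH4 = ", SGWP_CH4,
            " is outside the literature range [45, 96]", call. = FALSE)
  }
  structure(x, class = "flux_constants")
}

#' @export
print.flux_constants <- function(x, ...) {
  cat("Chamber flux constants:\n")
  for (nm in names(x)) cat(sprintf("  %-14s %g\n", nm, x[[nm]]))
  invisible(x)
}

# molar mass lookup for a gas label ("CO2" / "CH4")
gas_molar_mass <- function(gas, constants) {
  switch(gas,
         CO2 = constants$CO2_molar_mass,
         CH4 = constants$CH4_molar_mass,
         stop("unknown gas: '", gas, "'", call. = FALSE))
}
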