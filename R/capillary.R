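#' Capillary geometry and fluid parameters
#'
#' Describes the instrument's fused-silica capillary and the running fluid.
#' Defaults correspond to the standard setup: a 1 m capillary of 75 um inner
#' diameter, coiled with ~5 mm turn radius, run with water-like fluid
#' (viscosity 1e-3 Pa s, density 1e3 kg/m^3) at 3500 mbar, with a 50 um
#' detection window along the flow axis.
#'
#' @param length_m Capillary length L in m.
#' @param inner_diameter_m Inner diameter D in m.
#' @param turn_radius_m Coil turn radius R in m (for the Dean number).
#' @param pressure_mbar Driving pressure in mbar (1 mbar = 100 Pa).
#' @param viscosity_pa_s Dynamic viscosity mu in Pa s.
#' @param density_kg_m3 Fluid density rho in kg/m^3.
#' @param detection_window_m Length of the detection window in m.
#' @param temperature_k Capillary temperature in K (Stokes-Einstein).
#' @return A `capillary_system` list.
#' @examples
#' sys <- capillary_system()
#' flow_summary(sys)
#' @export
capillary_system <- function(length_m = 1,
                             inner_diameter_m = 75e-6,
                             turn_radius_m = 5e-3,
                             pressure_mbar = 3500,
                             viscosity_pa_s = 1e-3,
                             density_kg_m3 = 1e3,
                             detection_window_m = 50e-6,
                             temperature_k = 293.15) {
  vals <- c(length_m = length_m, inner_diameter_m = inner_diameter_m,
            turn_radius_m = turn_radius_m, pressure_mbar = pressure_mbar,
            viscosity_pa_s = viscosity_pa_s, density_kg_m3 = density_kg_m3,
            detection_window_m = detection_window_m,
            temperature_k = temperature_k)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (length(bad) > 0) {
    abort(sprintf("capillary_system parameters must be strictly positive: %s",
                  paste(bad, collapse = ", ")),
          class = "capflowr_validation_error")
  }
  if (inner_diameter_m >= length_m / 100) {
    abort("Inner diameter must be much smaller than capillary length.",
          class = "capflowr_validation_error")
  }
  structure(
    list(length_m = length_m, inner_diameter_m = inner_diameter_m,
         turn_radius_m = turn_radius_m, pressure_mbar = pressure_mbar,
         pressure_pa = pressure_mbar * 100,
         viscosity_pa_s = viscosity_pa_s, density_kg_m3 = density_kg_m3,
         detection_window_m = detection_window_m,
         temperature_k = temperature_k),
    class = "capillary_system"
  )
}

#' @export
print.capillary_system <- function(x, ...) {
  cat(sprintf(
    "<capillary_system> L=%.3g m, D=%.3g um, dP=%.4g mbar, mu=%.3g Pa s, T=%.5g K\n",
    x$length_m, x$inner_diameter_m * 1e6, x$pressure_mbar, x$viscosity_pa_s,
    x$temperature_k))
  invisible(x)
}
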