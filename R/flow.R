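#' Capillary flow physics
#'
#' Closed-form flow quantities for pressure-driven laminar (Poiseuille) flow
#' in the capillary: maximum (centreline) and mean velocity, dead time
#' (centre-streamline arrival at the detector), fill time, Reynolds and Dean
#' numbers, inertial focusing length and wall shear stress.
#'
#' Two modes are available.  `"physical"` evaluates the standard
#' Hagen-Poiseuille forms: the centreline velocity is
#' `u_max = dP * D^2 / (16 * mu * L)` and the cross-section mean is
#' `u_mean = u_max / 2`.  `"order_of_magnitude"` reproduces a coarse
#' substitution chain sometimes used to screen these quantities
#' (`dP * D^2 / (8 * mu * L)`, reported to the nearest power of ten); it is
#' intended only for order-of-magnitude screening of focusing and secondary
#' flow, not for quantitative work.
#'
#' @param system A [capillary_system()].
#' @param mode `"physical"` (default) or `"order_of_magnitude"`.
#' @return Velocity in m/s.
#' @examples
#' sys <- capillary_system(pressure_mbar = 3500)
#' max_velocity(sys)        # ~0.123 m/s
#' dead_time(sys)           # ~8.1 s
#' @export
max_velocity <- function(system, mode = c("physical", "order_of_magnitude")) {
  mode <- match.arg(mode)
  u <- with(system, pressure_pa * inner_diameter_m^2 /
              (16 * viscosity_pa_s * length_m))
  if (mode == "order_of_magnitude") {
    u <- with(system, pressure_pa * inner_diameter_m^2 /
                (8 * viscosity_pa_s * length_m))
    u <- pow10_round(u)
  }
  u
}

# nearest power of ten (0 maps to 0)
pow10_round <- function(x) ifelse(x == 0, 0, 10^round(log10(abs(x))) * sign(x))

#' @rdname max_velocity
#' @export
mean_velocity <- function(system) max_velocity(system) / 2

#' Dead time and fill time
#'
#' The dead time is the time for the solution front (fastest, centreline
#' streamline) to reach the detector: `L / u_max`.  The fill time is the
#' time to inject one capillary volume, `L / u_mean = 2 * dead_time`; the
#' two are reported distinctly because the front arrival and the complete
#' exchange of the capillary content are different events.
#'
#' @inheritParams max_velocity
#' @return Time in seconds.
#' @export
dead_time <- function(system) system$length_m / max_velocity(system)

#' @rdname dead_time
#' @export
fill_time <- function(system) system$length_m / mean_velocity(system)

#' Reynolds number
#'
#' `Re = rho * u * D / mu` for a given velocity scale.
#'
#' @inheritParams max_velocity
#' @param velocity Velocity scale in m/s (default: mean velocity).
#' @return Dimensionless Reynolds number.
#' @export
reynolds <- function(system, velocity = mean_velocity(system)) {
  with(system, density_kg_m3 * velocity * inner_diameter_m / viscosity_pa_s)
}

#' Dean number of the coiled capillary
#'
#' `k = sqrt(D / (2 * R_turn)) * Re`.  Secondary (Dean) flow is negligible
#' when k is well below one.
#'
#' @inheritParams max_velocity
#' @param re Reynolds number to use (default: from the system's mean velocity).
#' @return Dimensionless Dean number.
#' @export
dean_number <- function(system, re = reynolds(system)) {
  sqrt(system$inner_diameter_m / (2 * system$turn_radius_m)) * re
}

#' Inertial focusing length
#'
#' Channel length needed for lift forces to migrate particles of radius `a`
#' to their equilibrium radial positions:
#' `L_f = pi * mu * D^2 / (rho * U_m * a^2 * f_e)`.  When `L_f` greatly
#' exceeds the capillary length, particles stay randomly distributed over
#' the cross-section.
#'
#' @inheritParams max_velocity
#' @param particle_radius_m Particle radius a in m.
#' @param lift_factor Empirical lift-force factor f_e, usually 0.02-0.05.
#' @param u_m Velocity scale U_m in m/s (default: the system's maximum
#'   velocity in the requested mode).
#' @return Length in m.
#' @export
focusing_length <- function(system, particle_radius_m,
                            lift_factor = 0.05,
                            mode = c("physical", "order_of_magnitude"),
                            u_m = max_velocity(system, mode)) {
  mode <- match.arg(mode)
  if (particle_radius_m <= 0) {
    abort("particle_radius_m must be positive.",
          class = "capflowr_validation_error")
  }
  if (lift_factor <= 0 || lift_factor > 0.1) {
    abort("lift_factor must be in (0, 0.1].",
          class = "capflowr_validation_error")
  }
  lf <- with(system, pi * viscosity_pa_s * inner_diameter_m^2 /
               (density_kg_m3 * u_m * particle_radius_m^2 * lift_factor))
  if (mode == "order_of_magnitude") lf <- signif(lf, 1)
  lf
}

#' Wall shear stress
#'
#' `tau_w = gamma_w * mu = (8 * u_mean / D) * mu`, the standard result for
#' pipe flow evaluated at the cross-section mean velocity.  Supplying
#' `velocity` overrides the velocity scale, which supports
#' order-of-magnitude screening with a caller-chosen U.
#'
#' @inheritParams max_velocity
#' @param velocity Velocity scale in m/s (default: mean velocity).
#' @return Shear stress in Pa.
#' @export
wall_shear_stress <- function(system, velocity = mean_velocity(system)) {
  8 * velocity * system$viscosity_pa_s / system$inner_diameter_m
}

#' All derived flow quantities as a one-row tibble
#'
#' Convenience wrapper evaluating every flow quantity for a system.  The
#' `shear_reference_pa` column carries the commonly quoted ~2 Pa
#' order-of-magnitude wall-shear reference for this class of setup; it is
#' not derivable from the physical velocities reported here (see the
#' `shear_discrepancy` flag) and is retained only for comparison against
#' droplet-deformation thresholds from the literature.
#'
#' @inheritParams max_velocity
#' @param particle_radius_m Particle radius for the focusing length (default
#'   0.5 um, a 1-um-diameter calibration sphere).
#' @param lift_factor Lift-force factor for the focusing length.
#' @return A one-row tibble of flow quantities.
#' @export
flow_summary <- function(system, mode = c("physical", "order_of_magnitude"),
                         particle_radius_m = 0.5e-6, lift_factor = 0.05) {
  mode <- match.arg(mode)
  umax <- max_velocity(system, mode)
  umean <- if (mode == "physical") umax / 2 else umax / 2
  re <- reynolds(system, umean)
  tau <- wall_shear_stress(system, umean)
  tibble::tibble(
    mode = mode,
    u_max_m_s = umax,
    u_mean_m_s = umean,
    dead_time_s = system$length_m / umax,
    fill_time_s = system$length_m / umean,
    reynolds = re,
    dean_k = dean_number(system, re),
    focusing_length_m = focusing_length(system, particle_radius_m,
                                        lift_factor, mode, u_m = umax),
    wall_shear_pa = tau,
    shear_reference_pa = 2,
    shear_discrepancy = abs(tau / 2 - 1) > 0.5
  )
}
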