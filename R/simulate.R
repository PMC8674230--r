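#' Ground truth for a synthetic capillary-flow sample
#'
#' Bundles the known quantities a simulated sample is generated from, so
#' every analysis stage can be checked against truth: the total and
#' dilute-phase concentrations (their difference is what partitioned into
#' droplets), the labeled fraction, the droplet census and volume
#' distribution, and the seed.
#'
#' @param total_conc_um Total labeled-species-equivalent concentration, uM.
#' @param dilute_conc_um Dilute-phase concentration, uM
#'   (`0 < dilute <= total`).
#' @param label_fraction Fraction of the species carrying the fluorophore,
#'   in (0, 1].  Signal is proportional to labeled concentration; with the
#'   calibration expressed per total uM this stays at 1.
#' @param droplet_count Number of droplets crossing the detector.
#' @param volume_meanlog,volume_sdlog Parameters of the lognormal droplet
#'   volume distribution (arbitrary volume units); lognormal because droplet
#'   volumes are positive and right-skewed.
#' @param enrichment_factor Relative enrichment carried as ground truth for
#'   paired-label simulations.
#' @param seed Integer seed; mandatory for any stochastic use.
#' @return A `synthetic_ground_truth` list.
#' @export
synthetic_ground_truth <- function(total_conc_um, dilute_conc_um,
                                   label_fraction = 1,
                                   droplet_count = 0,
                                   volume_meanlog = 0, volume_sdlog = 0.5,
                                   enrichment_factor = 1,
                                   seed = NULL) {
  if (!(dilute_conc_um > 0 && dilute_conc_um <= total_conc_um)) {
    abort("Need 0 < dilute_conc_um <= total_conc_um.",
          class = "capflowr_validation_error")
  }
  if (!(label_fraction > 0 && label_fraction <= 1)) {
    abort("label_fraction must be in (0, 1].",
          class = "capflowr_validation_error")
  }
  if (droplet_count < 0) {
    abort("droplet_count must be >= 0.", class = "capflowr_validation_error")
  }
  structure(
    list(total_conc_um = total_conc_um, dilute_conc_um = dilute_conc_um,
         label_fraction = label_fraction,
         droplet_count = as.integer(droplet_count),
         volume_meanlog = volume_meanlog, volume_sdlog = volume_sdlog,
         enrichment_factor = enrichment_factor, seed = seed),
    class = "synthetic_ground_truth"
  )
}

#' Configuration of a synthetic trace
#'
#' Collects everything the simulator needs: the capillary system (geometry,
#' pressure, fluid), the sample ground truth, the detector model (sampling
#' rate, Gaussian noise, saturation ceiling at 50 FU), the calibration
#' mapping concentration to baseline FU, the droplet brightness scale, and
#' the model variants (radial density mode, front shape).
#'
#' @param system A [capillary_system()].
#' @param ground_truth A [synthetic_ground_truth()].
#' @param noise_sd_fu Gaussian detector noise sd, FU.
#' @param saturation_ceiling_fu Detector ceiling, FU (default 50).
#' @param sampling_rate_hz Detector sampling rate, Hz.
#' @param duration_s Acquisition length, s.
#' @param fu_per_um Calibration slope used to map dilute concentration to
#'   baseline FU (FU per uM).
#' @param intercept_fu Calibration intercept, FU.
#' @param brightness_fu_per_vol Spike amplitude per unit droplet volume,
#'   FU; spike amplitude is brightness x volume (peak height scales with
#'   droplet volume), clipped at the saturation ceiling.
#' @param radial_pdf_mode `"empirical"` (particle flux proportional to
#'   `(1 - r/R)^2 * r`, the law fitted to monodisperse-sphere calibration
#'   data) or `"poiseuille"` (standard flux weighting
#'   `(1 - (r/R)^2) * r`).
#' @param front_mode `"logistic"` (default; 4-parameter logistic with
#'   midpoint just past the dead time, so the plateau is reached on a
#'   realistic acquisition) or `"hydrodynamic"`
#'   (`f(t) = max(0, 1 - t0/t)`, the ideal plug-geometry fill fraction).
#' @param plug_flow Force a uniform velocity profile (all droplets at the
#'   centreline velocity); used to isolate volume effects from residence
#'   effects.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(system = capillary_system(),
                              ground_truth,
                              noise_sd_fu = 0.05,
                              saturation_ceiling_fu = 50,
                              sampling_rate_hz = 10,
                              duration_s = 60,
                              fu_per_um = 0.05,
                              intercept_fu = 0,
                              brightness_fu_per_vol = 2,
                              radial_pdf_mode = c("empirical", "poiseuille"),
                              front_mode = c("logistic", "hydrodynamic"),
                              plug_flow = FALSE) {
  radial_pdf_mode <- match.arg(radial_pdf_mode)
  front_mode <- match.arg(front_mode)
  stopifnot(inherits(system, "capillary_system"),
            inherits(ground_truth, "synthetic_ground_truth"))
  if (!(saturation_ceiling_fu > noise_sd_fu && noise_sd_fu >= 0)) {
    abort("Need saturation_ceiling_fu > noise_sd_fu >= 0.",
          class = "capflowr_validation_error")
  }
  if (sampling_rate_hz <= 0 || duration_s <= 0) {
    abort("sampling_rate_hz and duration_s must be positive.",
          class = "capflowr_validation_error")
  }
  structure(
    list(system = system, ground_truth = ground_truth,
         noise_sd_fu = noise_sd_fu,
         saturation_ceiling_fu = saturation_ceiling_fu,
         sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
         fu_per_um = fu_per_um, intercept_fu = intercept_fu,
         brightness_fu_per_vol = brightness_fu_per_vol,
         radial_pdf_mode = radial_pdf_mode, front_mode = front_mode,
         plug_flow = plug_flow),
    class = "simulation_config"
  )
}

#' Local flow velocity at radial position r
#'
#' Poiseuille profile `u(r) = u_max * (1 - (2 r / D)^2)` with the centreline
#' velocity from [max_velocity()].
#'
#' @param system A [capillary_system()].
#' @param r_m Radial position(s) in m, `0 <= r < D/2`.
#' @return Velocity in m/s.
#' @export
local_velocity <- function(system, r_m) {
  radius <- system$inner_diameter_m / 2
  if (any(r_m < 0 | r_m >= radius)) {
    abort("Radial position must satisfy 0 <= r < D/2.",
          class = "capflowr_domain_error")
  }
  max_velocity(system) * (1 - (r_m / radius)^2)
}

#' Radial particle density across the capillary cross-section
#'
#' Normalized density of the radial position (as a fraction `x = r/R` of the
#' inner radius) at which a randomly distributed particle crosses the
#' detector.  `"empirical"` mode uses flux proportional to
#' `(1 - x)^2 * x` (density `12 * (1 - x)^2 * x`); `"poiseuille"` mode uses
#' the standard flux weighting `(1 - x^2) * x` (density `4 * (1 - x^2) * x`).
#' Both vanish at the centreline and at the wall.
#'
#' @param x Relative radius in `[0, 1]`.
#' @param mode `"empirical"` or `"poiseuille"`.
#' @return Density values (or cumulative probabilities for `radial_cdf`).
#' @export
radial_pdf <- function(x, mode = c("empirical", "poiseuille")) {
  mode <- match.arg(mode)
  out <- switch(mode,
                empirical = 12 * (1 - x)^2 * x,
                poiseuille = 4 * (1 - x^2) * x)
  out[x < 0 | x > 1] <- 0
  out
}

#' @rdname radial_pdf
#' @export
radial_cdf <- function(x, mode = c("empirical", "poiseuille")) {
  mode <- match.arg(mode)
  x <- pmin(pmax(x, 0), 1)
  switch(mode,
         empirical = 6 * x^2 - 8 * x^3 + 3 * x^4,
         poiseuille = 2 * x^2 - x^4)
}

#' Draw radial positions for droplets crossing the detector
#'
#' Inverse-CDF sampling from [radial_pdf()]; the closed-form CDF is
#' inverted on a dense monotone grid.
#'
#' @param n Number of draws.
#' @param system A [capillary_system()] (sets the inner radius).
#' @param mode `"empirical"` or `"poiseuille"`.
#' @param seed Optional integer seed (set it here or upstream).
#' @return Radial positions in m, in `[0, D/2)`.
#' @export
sample_radial_position <- function(n, system = capillary_system(),
                                   mode = c("empirical", "poiseuille"),
                                   seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  x <- sample_relative_radius(n, mode)
  x * system$inner_diameter_m / 2
}

sample_relative_radius <- function(n, mode) {
  grid <- seq(0, 1, length.out = 4001)
  cdf <- radial_cdf(grid, mode)
  u <- runif(n)
  # CDF strictly increasing on (0,1); inverse by interpolation
  pmin(approx(cdf, grid, xout = u, ties = "ordered")$y, 1 - 1e-12)
}

#' Simulate the sigmoidal solution front
#'
#' Signal of a droplet-free injection: zero before the dead time, rising to
#' the dilute-phase plateau as the solution front fills the detector
#' cross-section.  `"hydrodynamic"` mode uses the ideal fill fraction
#' `f(t) = max(0, 1 - t0/t)` (50% of the plateau at exactly `2 t0`);
#' `"logistic"` mode uses a 4-parameter logistic with midpoint `1.2 t0` and
#' rate `10 / t0`, which reaches 99% of the plateau by about `1.7 t0`.
#'
#' @param config A [simulation_config()].
#' @param time_s Optional time grid (defaults to the config's grid).
#' @return A tibble `time_s`, `signal_fu` (noise-free, no droplets).
#' @export
simulate_front <- function(config, time_s = NULL) {
  if (is.null(time_s)) {
    time_s <- config_time_grid(config)
  }
  t0 <- dead_time(config$system)
  plateau <- config$intercept_fu +
    config$fu_per_um * config$ground_truth$dilute_conc_um
  f <- switch(config$front_mode,
              hydrodynamic = ifelse(time_s <= t0, 0, 1 - t0 / time_s),
              logistic = 1 / (1 + exp(-(10 / t0) * (time_s - 1.2 * t0))))
  tibble::tibble(time_s = time_s, signal_fu = plateau * pmax(f, 0))
}

config_time_grid <- function(config) {
  seq(0, config$duration_s, by = 1 / config$sampling_rate_hz)
}

# time at which the simulated front reaches 99% of its plateau
front_settle_time <- function(config) {
  t0 <- dead_time(config$system)
  switch(config$front_mode,
         hydrodynamic = 100 * t0,
         logistic = 1.2 * t0 + log(99) * t0 / 10)
}

#' Simulate a full capillary-flow trace with droplet spikes
#'
#' Builds a trace as front + flat dilute-phase baseline + droplet spikes +
#' Gaussian noise, with detector clipping at the saturation ceiling, and
#' returns the ground-truth droplet events alongside.
#'
#' Each droplet enters at a uniformly drawn time after the front has
#' settled, at a radial position drawn from [radial_pdf()], with a lognormal
#' volume.  Its spike has amplitude `brightness_fu_per_vol * volume` and
#' residence duration `detection_window / u(r)`; every sample inside the
#' residence window is raised by the full amplitude (a spike narrower than
#' one sampling interval lands on the nearest sample at full amplitude, so
#' peak height -- the observable that scales with droplet volume -- is
#' preserved regardless of sampling).  Overlapping spikes add linearly
#' before clipping, as fluorescence does.
#'
#' @param config A [simulation_config()]; `config$ground_truth$seed` must be
#'   set unless `events` is supplied.
#' @param events Optional tibble of pre-specified droplet events with
#'   columns `entry_time_s`, `amplitude_fu` and optionally `width_s`
#'   (defaults to one sampling interval) -- used for deterministic fixtures.
#' @return A list with `trace` (a [cap_trace()]), `events` (ground-truth
#'   droplet table with deposited areas), `baseline_fu` (noise-free plateau),
#'   `baseline_area_fu_s` (noise-free area of front + baseline) and
#'   `settle_time_s`.
#' @export
simulate_trace <- function(config, events = NULL) {
  gt <- config$ground_truth
  if (is.null(events)) {
    if (is.null(gt$seed)) {
      abort("Stochastic simulation requires an explicit seed in the ground truth.",
            class = "capflowr_config_error")
    }
    set.seed(gt$seed)
  }
  time_s <- config_time_grid(config)
  dt <- 1 / config$sampling_rate_hz
  front <- simulate_front(config, time_s)
  signal <- front$signal_fu
  t_settle <- min(front_settle_time(config), config$duration_s)
  baseline_fu <- config$intercept_fu + config$fu_per_um * gt$dilute_conc_um

  if (is.null(events)) {
    n <- gt$droplet_count
    if (n > 0) {
      entry <- sort(runif(n, t_settle, config$duration_s))
      radius <- config$system$inner_diameter_m / 2
      r <- if (config$plug_flow) rep(0, n) else
        sample_relative_radius(n, config$radial_pdf_mode) * radius
      u <- max_velocity(config$system) * (1 - (r / radius)^2)
      volume <- rlnorm(n, gt$volume_meanlog, gt$volume_sdlog)
      events <- tibble::tibble(
        entry_time_s = entry,
        radial_pos_m = r,
        volume = volume,
        amplitude_fu = config$brightness_fu_per_vol * volume,
        width_s = config$system$detection_window_m / u
      )
    } else {
      events <- tibble::tibble(entry_time_s = numeric(0),
                               radial_pos_m = numeric(0), volume = numeric(0),
                               amplitude_fu = numeric(0), width_s = numeric(0))
    }
  } else {
    events <- tibble::as_tibble(events)
    if (!"width_s" %in% names(events)) events$width_s <- dt
  }

  deposited <- numeric(nrow(events))
  n_samp <- integer(nrow(events))
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      idx <- which(time_s >= events$entry_time_s[i] &
                     time_s <= events$entry_time_s[i] + events$width_s[i])
      if (length(idx) == 0) {
        idx <- which.min(abs(time_s - events$entry_time_s[i]))
      }
      signal[idx] <- signal[idx] + events$amplitude_fu[i]
      n_samp[i] <- length(idx)
      deposited[i] <- events$amplitude_fu[i] * length(idx) * dt
    }
  }
  events$n_samples <- n_samp
  events$deposited_area_fu_s <- deposited

  clipped <- pmin(signal, config$saturation_ceiling_fu)
  if (config$noise_sd_fu > 0) {
    clipped <- clipped + rnorm(length(clipped), 0, config$noise_sd_fu)
  }
  trace <- cap_trace(time_s, clipped, channel = "alexa488",
                     pressure_mbar = config$system$pressure_mbar,
                     sample_id = "synthetic",
                     metadata = list(synthetic = TRUE, seed = gt$seed))
  list(trace = trace, events = events, baseline_fu = baseline_fu,
       baseline_area_fu_s = trapz(time_s, front$signal_fu),
       settle_time_s = t_settle)
}

#' Stokes-Einstein diffusion coefficient
#'
#' `D = kB * T / (6 * pi * mu * R_h)`.
#'
#' @param r_h_nm Hydrodynamic radius in nm.
#' @param temperature_k Temperature in K.
#' @param viscosity_pa_s Dynamic viscosity in Pa s.
#' @return Diffusion coefficient in m^2/s.
#' @export
stokes_einstein_d <- function(r_h_nm, temperature_k = 293.15,
                              viscosity_pa_s = 1e-3) {
  .kB * temperature_k / (6 * pi * viscosity_pa_s * r_h_nm * 1e-9)
}

#' Simulate a Taylorgram
#'
#' A small plug of labeled molecules dispersed by laminar flow arrives at
#' the detector as a Gaussian peak centred at the residence time `t_R` with
#' temporal variance `sigma_t^2 = r_c^2 * t_R / (24 * D)`, where `r_c = D/2`
#' is the capillary inner radius and `D` the analyte diffusivity from the
#' Stokes-Einstein relation at the system temperature.  Smaller molecules
#' diffuse faster and give narrower peaks.
#'
#' @param r_h_nm Hydrodynamic radius of the labeled species, nm.
#' @param system A [capillary_system()].
#' @param residence_time_s Peak centre t_R in s.
#' @param amplitude_fu Peak amplitude, FU.
#' @param noise_sd_fu Gaussian noise sd, FU.
#' @param sampling_rate_hz Detector sampling rate, Hz.
#' @param seed Integer seed (required when `noise_sd_fu > 0`).
#' @return A [cap_trace()] spanning `t_R +/- 6 sigma_t`.
#' @export
simulate_taylorgram <- function(r_h_nm, system = capillary_system(),
                                residence_time_s, amplitude_fu = 10,
                                noise_sd_fu = 0, sampling_rate_hz = 10,
                                seed = NULL) {
  stopifnot(r_h_nm > 0, residence_time_s > 0)
  d_diff <- stokes_einstein_d(r_h_nm, system$temperature_k,
                              system$viscosity_pa_s)
  r_c <- system$inner_diameter_m / 2
  sigma2 <- r_c^2 * residence_time_s / (24 * d_diff)
  sigma <- sqrt(sigma2)
  dt <- 1 / sampling_rate_hz
  if (sigma < 3 * dt) {
    abort(sprintf("Taylorgram peak (sigma = %.3g s) narrower than 3 sampling intervals; increase sampling_rate_hz.",
                  sigma),
          class = "capflowr_sampling_error")
  }
  t <- seq(max(0, residence_time_s - 6 * sigma), residence_time_s + 6 * sigma,
           by = dt)
  y <- amplitude_fu * exp(-(t - residence_time_s)^2 / (2 * sigma2))
  if (noise_sd_fu > 0) {
    if (is.null(seed)) {
      abort("Noisy Taylorgram simulation requires an explicit seed.",
            class = "capflowr_config_error")
    }
    set.seed(seed)
    y <- y + rnorm(length(y), 0, noise_sd_fu)
  }
  cap_trace(t, y, channel = "alexa488",
            pressure_mbar = system$pressure_mbar,
            sample_id = "synthetic_taylorgram",
            metadata = list(synthetic = TRUE, r_h_nm = r_h_nm,
                            sigma_s = sigma))
}
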