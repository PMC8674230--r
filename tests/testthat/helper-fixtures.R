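# Shared fixtures, all generated in code.

# calibration with slope 0.05 FU/uM, zero intercept
std_cal <- function() fit_standard_curve(c(10, 20, 50), c(0.5, 1.0, 2.5))

# simulated LLPS sample at given total/dilute concentration
sim_llps <- function(total_um, dilute_um, n_droplets, seed, noise_sd = 0.05,
                     duration_s = 120, ...) {
  gt <- synthetic_ground_truth(total_um, dilute_um,
                               droplet_count = n_droplets, seed = seed)
  cfg <- simulation_config(ground_truth = gt, noise_sd_fu = noise_sd,
                           duration_s = duration_s, ...)
  c(simulate_trace(cfg), list(config = cfg))
}

# trace restricted to the post-front (settled) region
post_front_trace <- function(sim) {
  keep <- sim$trace$time_s >= sim$settle_time_s
  cap_trace(sim$trace$time_s[keep], sim$trace$signal_fu[keep])
}

# deterministic non-overlapping droplet events
events_nonoverlap <- function(n, amplitude_fu = 0.5, start_s = 20,
                              spacing_s = 0.5) {
  tibble::tibble(entry_time_s = start_s + spacing_s * (seq_len(n) - 1),
                 amplitude_fu = rep_len(amplitude_fu, n))
}

# paired simulations whose droplet-phase signal fractions are set exactly,
# for enrichment recovery against known ground truth
sim_enrichment_member <- function(spike_fraction, seed, noise_sd = 0,
                                  n_droplets = 150, duration_s = 120) {
  # low dilute-phase baseline keeps rescaled spikes clear of the 50-FU
  # detector ceiling for all tested fractions
  gt <- synthetic_ground_truth(100, 30, droplet_count = n_droplets,
                               seed = seed)
  cfg <- simulation_config(ground_truth = gt, noise_sd_fu = 0,
                           duration_s = duration_s)
  draft <- simulate_trace(cfg)
  base_area <- draft$baseline_fu * (duration_s - draft$settle_time_s)
  target_area <- spike_fraction / (1 - spike_fraction) * base_area
  ev <- draft$events
  ev$amplitude_fu <- ev$amplitude_fu * target_area /
    sum(ev$deposited_area_fu_s)
  sim <- simulate_trace(cfg, events = ev[, c("entry_time_s", "amplitude_fu",
                                             "width_s")])
  if (noise_sd > 0) {
    set.seed(seed + 5000L)
    sim$trace$signal_fu <- sim$trace$signal_fu +
      rnorm(nrow(sim$trace), 0, noise_sd)
  }
  sim
}

measure_enrichment <- function(frac_a, frac_b, seed_a, seed_b, noise_sd = 0) {
  sim_a <- sim_enrichment_member(frac_a, seed_a, noise_sd)
  sim_b <- sim_enrichment_member(frac_b, seed_b, noise_sd)
  relative_enrichment(post_front_trace(sim_a), post_front_trace(sim_b),
                      sim_a$baseline_fu, sim_b$baseline_fu)$enrichment
}

# Dense-matrix reimplementation of the ALS iteration used as the oracle:
# identical weight-update rule, base-R solve on the full penalized system.
dense_als_iterates <- function(y, p = 0.001, lambda = 1e4, iterations = 20,
                               conv_tol = 0.005) {
  n <- length(y)
  d2 <- diff(diag(n), differences = 2)
  penalty <- lambda * crossprod(d2)
  w <- rep(1, n)
  z <- y
  out <- list()
  for (it in seq_len(iterations)) {
    z_new <- solve(penalty + diag(w), w * y)
    out[[it]] <- z_new
    rel_change <- max(abs(z_new - z) / pmax(abs(z), 1e-12))
    conv <- it > 1 && rel_change < conv_tol
    z <- z_new
    w <- ifelse(y > z, p, 1 - p)
    if (conv) break
  }
  out
}

# noise-free synthetic titration for a binding model
make_titration <- function(model, analyte_um = c(0, 0.5, 1, 2, 4, 6, 10,
                                                 20, 50, 100, 200, 358)) {
  tibble::tibble(analyte_um = analyte_um,
                 rh_nm = binding_isotherm(model, analyte_um))
}
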