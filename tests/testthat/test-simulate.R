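test_that("local velocity follows the parabolic profile", {
  sys <- capillary_system(pressure_mbar = 3500, inner_diameter_m = 75e-6)
  umax <- 3.5e5 * (75e-6)^2 / (16 * 1e-3) # independent hand evaluation
  expect_equal(local_velocity(sys, 0), umax, tolerance = 1e-12)
  r_wall <- 37.5e-6 * (1 - 1e-8)
  expect_lt(local_velocity(sys, r_wall), umax * 1e-6) # no-slip limit
  expect_error(local_velocity(sys, 37.5e-6), class = "capflowr_domain_error")
  expect_error(local_velocity(sys, -1e-6), class = "capflowr_domain_error")
})

test_that("radial densities are normalized with zero boundary mass", {
  for (m in c("empirical", "poiseuille")) {
    expect_equal(integrate(radial_pdf, 0, 1, mode = m)$value, 1,
                 tolerance = 1e-8)
    expect_equal(radial_cdf(1, m), 1)
    expect_equal(radial_cdf(0, m), 0)
    expect_equal(radial_pdf(0, m), 0)
  }
  expect_equal(radial_pdf(1, "empirical"), 0)
})

test_that("radial sampling matches the closed-form CDF", {
  sys <- capillary_system()
  for (m in c("empirical", "poiseuille")) {
    r <- sample_radial_position(1e5, sys, mode = m, seed = 11)
    expect_true(all(r >= 0 & r < sys$inner_diameter_m / 2))
    x <- r / (sys$inner_diameter_m / 2)
    ks <- max(abs(seq_along(x) / length(x) - radial_cdf(sort(x), m)))
    expect_lt(ks, 0.01)
  }
})

test_that("the simulated front has the right geometry", {
  gt <- synthetic_ground_truth(100, 70, seed = 1)
  cfg_h <- simulation_config(ground_truth = gt, front_mode = "hydrodynamic",
                             duration_s = 2000)
  t0 <- dead_time(cfg_h$system)
  plateau <- 0.05 * 70
  fr <- simulate_front(cfg_h, time_s = c(t0 / 2, t0, 2 * t0, 1e7))
  expect_equal(fr$signal_fu[1:2], c(0, 0)) # pre-arrival
  expect_equal(fr$signal_fu[3], plateau / 2, tolerance = 1e-9) # half at 2 t0
  expect_equal(fr$signal_fu[4], plateau, tolerance = 1e-6) # asymptote

  cfg_l <- simulation_config(ground_truth = gt, front_mode = "logistic")
  fr_l <- simulate_front(cfg_l, time_s = c(0, 1.2 * t0, 1e5))
  expect_lt(fr_l$signal_fu[1], 0.01 * plateau)
  expect_equal(fr_l$signal_fu[2], plateau / 2, tolerance = 1e-9) # midpoint
  expect_equal(fr_l$signal_fu[3], plateau, tolerance = 1e-9)
})

test_that("a droplet-free trace never strays far above its baseline", {
  sim <- sim_llps(100, 70, 0, seed = 5, noise_sd = 0.05, duration_s = 60)
  post <- post_front_trace(sim)
  expect_true(all(post$signal_fu <= sim$baseline_fu + 5 * 0.05))
})

test_that("identical seeds give bit-identical traces", {
  a <- sim_llps(100, 70, 50, seed = 123, noise_sd = 0.05)
  b <- sim_llps(100, 70, 50, seed = 123, noise_sd = 0.05)
  expect_identical(a$trace$signal_fu, b$trace$signal_fu)
  expect_identical(a$events, b$events)
  c <- sim_llps(100, 70, 50, seed = 124, noise_sd = 0.05)
  expect_false(identical(a$trace$signal_fu, c$trace$signal_fu))
})

test_that("a missing seed on a stochastic simulation is a hard error", {
  gt <- synthetic_ground_truth(100, 70, droplet_count = 5)
  cfg <- simulation_config(ground_truth = gt)
  expect_error(simulate_trace(cfg), class = "capflowr_config_error")
})

test_that("a 0.3-FU droplet is detectable at the default threshold", {
  gt <- synthetic_ground_truth(100, 70, droplet_count = 0, seed = 9)
  cfg <- simulation_config(ground_truth = gt, noise_sd_fu = 0,
                           duration_s = 60)
  sim <- simulate_trace(cfg, events = events_nonoverlap(1, 0.3))
  bl <- extract_baseline(sim$trace, std_cal(), 100)
  pk <- detect_peaks(sim$trace, bl)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$height_fu, 0.3, tolerance = 0.01)
})

test_that("injected fluorescence is conserved through deposition and noise-free readout", {
  sim <- sim_llps(100, 70, 150, seed = 31, noise_sd = 0)
  total_area <- capflowr:::trapz(sim$trace$time_s, sim$trace$signal_fu)
  budget <- sim$baseline_area_fu_s + sum(sim$events$deposited_area_fu_s)
  # trapezoid vs per-sample deposition differ only at spike flanks
  expect_equal(total_area, budget, tolerance = 0.01)
})

test_that("plug flow turns monodisperse droplets into a single-valued height distribution", {
  gt <- synthetic_ground_truth(100, 70, droplet_count = 40,
                               volume_sdlog = 1e-12, seed = 17)
  cfg <- simulation_config(ground_truth = gt, noise_sd_fu = 0,
                           duration_s = 120, plug_flow = TRUE)
  sim <- simulate_trace(cfg)
  bl <- extract_baseline(sim$trace, std_cal(), 100)
  pk <- detect_peaks(sim$trace, bl)
  # judge heights on the settled plateau, away from the front tail
  settled <- pk$height_fu[pk$peak_time_s > 20]
  expect_gt(length(settled), 0)
  expect_lt(diff(range(settled)), 1e-3)
})

test_that("Taylorgram plugs encode diffusivity in their width", {
  sys <- capillary_system()
  # Stokes-Einstein at 2.3 nm, water, 20 C, evaluated by hand
  d_ref <- 1.380649e-23 * 293.15 / (6 * pi * 1e-3 * 2.3e-9)
  expect_equal(stokes_einstein_d(2.3), d_ref, tolerance = 1e-12)
  expect_equal(d_ref, 9.34e-11, tolerance = 0.01)

  tg1 <- simulate_taylorgram(2.3, sys, residence_time_s = 120)
  tg2 <- simulate_taylorgram(4.6, sys, residence_time_s = 120)
  s1 <- attr(tg1, "metadata")$sigma_s
  s2 <- attr(tg2, "metadata")$sigma_s
  expect_equal(s2^2 / s1^2, 2, tolerance = 1e-9) # doubling R_h doubles sigma^2

  expect_error(simulate_taylorgram(0.01, sys, residence_time_s = 1,
                                   sampling_rate_hz = 1),
               class = "capflowr_sampling_error")
})
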