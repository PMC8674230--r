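test_that("standard curves fit exactly on collinear points and reject bad input", {
  cal <- fit_standard_curve(c(10, 20, 50), c(1, 2, 5))
  expect_equal(cal$slope, 0.1, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_equal(invert_calibration(cal, 3.5), 35, tolerance = 1e-12)

  expect_error(fit_standard_curve(c(10, 10), c(1, 1.1)),
               class = "capflowr_calibration_error")
  expect_error(fit_standard_curve(c(10, 20, 50), c(5, 2, 1)),
               class = "capflowr_calibration_error")
})

test_that("noisy standards recover the slope within the OLS confidence interval", {
  # closed-form OLS in the test as the oracle
  set.seed(1234)
  covered <- 0
  for (i in 1:20) {
    conc <- c(5, 10, 20, 30, 40, 50)
    y <- 0.05 * conc + rnorm(6, 0, 0.01)
    cal <- fit_standard_curve(conc, y)
    sxx <- sum((conc - mean(conc))^2)
    slope_hat <- sum((conc - mean(conc)) * (y - mean(y))) / sxx
    expect_equal(cal$slope, slope_hat, tolerance = 1e-10)
    resid <- y - mean(y) - slope_hat * (conc - mean(conc))
    se <- sqrt(sum(resid^2) / 4 / sxx)
    expect_equal(cal$slope_se, se, tolerance = 1e-10)
    if (abs(0.05 - slope_hat) <= qt(0.975, 4) * se) covered <- covered + 1
  }
  expect_gte(covered, 17) # ~95% coverage over 20 draws
})

test_that("noise-free baseline extraction inverts the calibration exactly", {
  sim <- sim_llps(100, 70, 0, seed = 2, noise_sd = 0)
  bl <- extract_baseline(sim$trace, std_cal(), 100)
  # the baseline region opens at the 99% point of the front, so the lowest
  # filtered samples sit a hair below the plateau
  expect_equal(bl$baseline_fu, 3.5, tolerance = 1e-3)
  expect_equal(bl$dilute_conc_um, 70, tolerance = 1e-3)
  expect_lte(bl$front_time_s, bl$region_start_s)
  expect_gte(bl$baseline_fu, bl$sigmoid$lower - 1e-6)
  expect_lte(bl$baseline_fu, bl$sigmoid$upper + 1e-6)
})

test_that("dilute-phase concentration is recovered from spiky, noisy traces", {
  # phase-separated: total 100 uM, true dilute 70 uM, 200 droplet spikes
  sim <- sim_llps(100, 70, 200, seed = 42, noise_sd = 0.05)
  bl <- extract_baseline(sim$trace, std_cal(), 100)
  expect_equal(bl$dilute_conc_um, 70, tolerance = 2 / 70)

  # non-phase-separated control: dilute = total = 100 uM
  sim0 <- sim_llps(100, 100, 0, seed = 43, noise_sd = 0.05)
  bl0 <- extract_baseline(sim0$trace, std_cal(), 100)
  expect_equal(bl0$dilute_conc_um, 100, tolerance = 2 / 100)
})

test_that("baseline extraction errors are classified", {
  cal <- std_cal()
  flat <- cap_trace(seq(0, 5, by = 0.1), rep(1, 51))
  expect_error(extract_baseline(flat, cal, 100),
               class = "capflowr_front_error")
  short <- sim_llps(100, 70, 0, seed = 2, noise_sd = 0, duration_s = 15)
  expect_error(extract_baseline(short$trace, cal, 100),
               class = "capflowr_insufficient_data_error")
})

test_that("peak detection applies the absolute threshold above the baseline", {
  gt <- synthetic_ground_truth(100, 70, droplet_count = 0, seed = 4)
  cfg <- simulation_config(ground_truth = gt, noise_sd_fu = 0,
                           duration_s = 60)
  # one clear spike and one sub-threshold spike
  ev <- tibble::tibble(entry_time_s = c(25, 40), amplitude_fu = c(0.3, 0.1))
  sim <- simulate_trace(cfg, events = ev)
  bl <- extract_baseline(sim$trace, std_cal(), 100)
  pk <- detect_peaks(sim$trace, bl, threshold_fu = 0.2)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$height_fu, 0.3, tolerance = 0.01)
  expect_false(any(pk$saturated))

  # flat noise-free trace: no peaks
  sim0 <- simulate_trace(cfg)
  bl0 <- extract_baseline(sim0$trace, std_cal(), 100)
  expect_equal(nrow(detect_peaks(sim0$trace, bl0)), 0)
})

test_that("all non-overlapping supra-threshold spikes are counted exactly", {
  gt <- synthetic_ground_truth(100, 70, droplet_count = 0, seed = 6)
  cfg <- simulation_config(ground_truth = gt, noise_sd_fu = 0.02,
                           duration_s = 120)
  set.seed(88)
  n <- 150
  ev <- events_nonoverlap(n, amplitude_fu = runif(n, 0.35, 3), spacing_s = 0.6)
  sim <- simulate_trace(cfg, events = ev)
  bl <- extract_baseline(sim$trace, std_cal(), 100)
  pk <- detect_peaks(sim$trace, bl, threshold_fu = 0.2)
  expect_equal(nrow(pk), n)
  expect_true(all(abs(sort(pk$peak_time_s) - ev$entry_time_s) <= 0.2))
})

test_that("saturated peaks are flagged against the detector ceiling", {
  gt <- synthetic_ground_truth(100, 70, droplet_count = 0, seed = 7)
  cfg <- simulation_config(ground_truth = gt, noise_sd_fu = 0,
                           duration_s = 60)
  ev <- tibble::tibble(entry_time_s = c(25, 40), amplitude_fu = c(100, 1))
  sim <- simulate_trace(cfg, events = ev)
  expect_equal(max(sim$trace$signal_fu), 50) # ceiling applied
  bl <- extract_baseline(sim$trace, std_cal(), 100)
  pk <- detect_peaks(sim$trace, bl)
  expect_equal(nrow(pk), 2)
  expect_equal(sort(pk$saturated), c(FALSE, TRUE))
})

test_that("partitioned amount is a plain difference with a noise flag", {
  expect_equal(partitioned_amount(100, 70)$partitioned_um, 30)
  expect_equal(partitioned_amount(100, 100)$partitioned_um, 0)
  p <- partitioned_amount(50, 57)
  expect_equal(p$partitioned_um, -7)
  expect_true(p$within_noise)
  expect_false(partitioned_amount(100, 70)$within_noise)
})

test_that("reversibility requires nearly all spikes to vanish", {
  mk_peaks <- function(n) capflowr:::new_cap_peaks(
    tibble::tibble(peak_time_s = seq_len(n), height_fu = rep(1, n),
                   integral_fu_s = rep(0.1, n), saturated = rep(FALSE, n)),
    threshold_used = 0.2, baseline_fu = 3.5)
  expect_true(reversibility_check(mk_peaks(120), mk_peaks(0))$reversible)
  expect_false(reversibility_check(mk_peaks(120), mk_peaks(118))$reversible)
  expect_error(reversibility_check(mk_peaks(0), mk_peaks(0)),
               class = "capflowr_validation_error")

  # monotone in the required fraction
  verdicts <- sapply(seq(0.05, 0.95, by = 0.05), function(f) {
    reversibility_check(mk_peaks(100), mk_peaks(20),
                        min_fraction_lost = f)$reversible
  })
  expect_true(all(diff(as.integer(verdicts)) <= 0))
})

test_that("recovered dilute concentration tracks truth across a grid and ignores droplets", {
  cal <- std_cal()
  # inverse-calibration identity on a concentration grid (droplet-free)
  for (conc in c(20, 50, 80, 110)) {
    sim <- sim_llps(120, conc, 0, seed = 50 + conc, noise_sd = 0,
                    duration_s = 60)
    bl <- extract_baseline(sim$trace, cal, 120)
    expect_equal(bl$dilute_conc_um, conc, tolerance = 1e-3)
  }

  # droplet insensitivity: spikes occupy < 20% of samples
  base <- sim_llps(100, 70, 0, seed = 61, noise_sd = 0.02)
  spiky <- sim_llps(100, 70, 150, seed = 61, noise_sd = 0.02)
  c0 <- extract_baseline(base$trace, cal, 100)$dilute_conc_um
  c1 <- extract_baseline(spiky$trace, cal, 100)$dilute_conc_um
  expect_lt(abs(c1 - c0) / c0, 0.01)

  # monotone in the partitioned fraction
  rec <- sapply(c(100, 80, 60, 40), function(dc) {
    sim <- sim_llps(100, dc, 100, seed = 70, noise_sd = 0.02)
    extract_baseline(sim$trace, cal, 100)$dilute_conc_um
  })
  expect_true(all(diff(rec) < 0))
})
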