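make_kinetics_trace <- function(n = 200, baseline = 5, spikes = integer(0),
                                spike_fu = 3, noise_sd = 0, seed = 1,
                                drift = 0) {
  set.seed(seed)
  t <- seq(0, by = 0.1, length.out = n)
  y <- baseline + drift * t + rnorm(n, 0, noise_sd)
  y[spikes] <- y[spikes] + spike_fu
  cap_trace(t, y)
}

test_that("a constant trace is a fixed point of the ALS baseline", {
  tr <- make_kinetics_trace(200, baseline = 5)
  bl <- als_baseline(tr)
  expect_lt(max(abs(bl$baseline_fu - 5)), 1e-8)
})

test_that("the ALS baseline stays below isolated spikes", {
  # noise-free: only the spike samples may sit above the baseline
  tr <- make_kinetics_trace(400, spikes = c(60, 150, 290))
  bl <- als_baseline(tr, asymmetry_p = 0.001)
  # slack of 1e-3 FU absorbs the tiny smoothness-penalty ridge around spikes
  frac_below <- mean(bl$baseline_fu <= tr$signal_fu + 1e-3)
  expect_gte(frac_below, 1 - 2 * 0.001 - 0.05)
  expect_lt(max(abs(bl$baseline_fu - 5)) / 5, 0.001)

  # with detector noise the baseline still barely moves under spikes
  trn <- make_kinetics_trace(400, spikes = c(60, 150, 290), noise_sd = 0.02,
                             seed = 8)
  bln <- als_baseline(trn, asymmetry_p = 0.001)
  expect_lt(max(abs(bln$baseline_fu - 5)) / 5, 0.01)
})

test_that("sparse ALS matches the dense direct solve at every iteration", {
  tr <- make_kinetics_trace(200, spikes = c(40, 90, 160), noise_sd = 0.05,
                            seed = 12, drift = 0.05)
  bl <- als_baseline(tr, keep_iterations = TRUE)
  oracle <- dense_als_iterates(tr$signal_fu)
  iterates <- attr(bl, "iterates")
  expect_equal(length(iterates), length(oracle))
  for (k in seq_along(oracle)) {
    rel <- max(abs(iterates[[k]] - oracle[[k]]) / pmax(abs(oracle[[k]]), 1e-12))
    expect_lt(rel, 1e-8)
  }
})

test_that("ALS requires enough samples", {
  tr <- cap_trace(seq(0, 0.8, by = 0.1), rep(1, 9))
  expect_error(als_baseline(tr), class = "capflowr_insufficient_data_error")
})

test_that("the kinetic peak criterion is relative to the local baseline", {
  n <- 300
  tr <- make_kinetics_trace(n, baseline = 10)
  z <- rep(10, n)
  y1 <- tr$signal_fu
  y1[100] <- 10 * 1.005 # 0.5% above: not a peak
  y1[200] <- 10 * 1.02  # 2% above: a peak
  tr1 <- cap_trace(tr$time_s, y1)
  pk <- detect_kinetic_peaks(tr1, z)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$peak_time_s, tr$time_s[200])
  expect_equal(pk$height_fu, 0.2, tolerance = 1e-9)

  # droplet-free noise well under 1% of the baseline: no peaks
  tr2 <- make_kinetics_trace(n, baseline = 10, noise_sd = 0.01, seed = 3)
  expect_equal(nrow(detect_kinetic_peaks(tr2, rep(10, n))), 0)

  expect_error(detect_kinetic_peaks(tr1, rep(0, n)),
               class = "capflowr_validation_error")
})

test_that("kinetic peak times match simulated event times to one sample", {
  tr <- make_kinetics_trace(600, baseline = 5, noise_sd = 0.005, seed = 21)
  event_idx <- seq(50, 550, by = 25)
  y <- tr$signal_fu
  y[event_idx] <- y[event_idx] + 1.5
  trs <- cap_trace(tr$time_s, y)
  bl <- als_baseline(trs)
  pk <- detect_kinetic_peaks(trs, bl)
  expect_equal(nrow(pk), length(event_idx))
  expect_true(all(abs(sort(pk$peak_time_s) - tr$time_s[event_idx]) <= 0.1))
})

test_that("sliding averages reduce to known values and respect time order", {
  mk <- function(h, t = seq_along(h)) capflowr:::new_cap_peaks(
    tibble::tibble(peak_time_s = t, height_fu = h,
                   integral_fu_s = NA_real_, saturated = NA),
    threshold_used = 0.01)
  one <- sliding_peak_average(mk(rep(2.5, 10)))
  expect_equal(nrow(one), 1)
  expect_equal(one$mean_height_fu, 2.5)

  ser <- sliding_peak_average(mk(1:20))
  expect_equal(ser$mean_height_fu[1], 5.5)
  expect_equal(ser$mean_height_fu[nrow(ser)], 15.5)

  # order by time is what matters, not row order
  perm <- sample(20)
  ser2 <- sliding_peak_average(mk((1:20)[perm], t = (1:20)[perm]))
  expect_equal(ser2, ser)

  expect_warning(few <- sliding_peak_average(mk(1:5)), "Fewer peaks")
  expect_equal(nrow(few), 0)
})

test_that("onset and growth rate are recovered from synthetic kinetics", {
  # onset at 30 s, one spike per second thereafter
  t <- seq(0, 240, by = 0.1)
  y <- rep(10, length(t))
  ev_t <- seq(30, 238, by = 1)
  idx <- match(round(ev_t, 1), round(t, 1))
  y[idx] <- y[idx] + 0.5 + 0.01 * (ev_t - 30)
  tr <- cap_trace(t, y)
  bl <- als_baseline(tr)
  pk <- detect_kinetic_peaks(tr, bl)
  res <- onset_and_rate(pk)
  expect_equal(res$lag_time_s, 30, tolerance = 0.2)
  expect_false(res$no_peaks)

  # noise-free linear growth: OLS recovers the slope exactly (FU/min)
  h <- 1 + 0.02 * seq(0, 119)
  pk_lin <- capflowr:::new_cap_peaks(
    tibble::tibble(peak_time_s = seq(0, 119), height_fu = h,
                   integral_fu_s = NA_real_, saturated = NA),
    threshold_used = 0.01)
  res_lin <- onset_and_rate(pk_lin, fit_end_s = 120)
  expect_equal(res_lin$rate_fu_per_min, 0.02 * 60, tolerance = 1e-9)

  empty <- detect_kinetic_peaks(cap_trace(1:20, rep(10, 20)), rep(10, 20))
  res0 <- onset_and_rate(empty)
  expect_true(res0$no_peaks)
  expect_true(is.na(res0$lag_time_s))
  expect_equal(res0$rate_fu_per_min, 0)
})
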