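# literal transcription of the published isotherm forms, used as the oracle
literal_isotherm <- function(a, kd, ru, rb, n) {
  x <- (1 / kd)^n * a^n
  (1 + x) / ((ru^-1 - rb^-1) + (1 + x) * rb^-1)
}

test_that("Taylorgram analysis round-trips the simulated hydrodynamic radius", {
  sys <- capillary_system()
  tg <- simulate_taylorgram(2.3, sys, residence_time_s = 120)
  fit <- taylorgram_rh(tg, sys)
  expect_equal(fit$r_h_nm, 2.3, tolerance = 0.02)
  expect_equal(fit$t_r_s, 120, tolerance = 0.01)

  # and with mild noise
  tgn <- simulate_taylorgram(2.3, sys, residence_time_s = 120,
                             noise_sd_fu = 0.05, seed = 5)
  expect_equal(taylorgram_rh(tgn, sys)$r_h_nm, 2.3, tolerance = 0.05)
})

test_that("reported radius follows the Stokes-Einstein scalings", {
  sys <- capillary_system()
  tg <- simulate_taylorgram(3, sys, residence_time_s = 100)
  base <- taylorgram_rh(tg, sys)
  # doubling viscosity at fixed trace: same measured D, R_h = kT/(6 pi mu D)
  sys2 <- capillary_system(viscosity_pa_s = 2e-3)
  halved <- taylorgram_rh(tg, sys2)
  expect_equal(halved$d_m2_s, base$d_m2_s, tolerance = 1e-9)
  expect_equal(halved$r_h_nm, base$r_h_nm / 2, tolerance = 1e-6)

  # quadrupling sigma_t^2 at fixed t_R quarters D and quadruples R_h
  wide <- cap_trace(tg$time_s, approx(tg$time_s, tg$signal_fu,
                                      xout = 100 + (tg$time_s - 100) / 2,
                                      rule = 2)$y)
  fit_w <- taylorgram_rh(wide, sys)
  expect_equal(fit_w$d_m2_s, base$d_m2_s / 4, tolerance = 0.02)
  expect_equal(fit_w$r_h_nm, base$r_h_nm * 4, tolerance = 0.02)
})

test_that("binding isotherms honour their limits and the half-saturation form", {
  for (n in 1:3) {
    m <- binding_model(n, 50, 3.5, 7)
    expect_equal(binding_isotherm(m, 0), 3.5, tolerance = 1e-12)
    expect_equal(binding_isotherm(m, 1e9), 7, tolerance = 1e-4)
  }
  m1 <- binding_model(1, 50, 3.5, 7)
  # half saturation at [A] = K_d: harmonic mean of the radii
  expect_equal(binding_isotherm(m1, 50), 2 * 3.5 * 7 / (3.5 + 7),
               tolerance = 1e-12)
})

test_that("the Hill form equals the literal isotherm on random parameter draws", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(1:3, 1)
    kd <- runif(1, 0.5, 200)
    ru <- runif(1, 0.5, 10)
    rb <- runif(1, 0.5, 10)
    a <- runif(8, 0, 500)
    m <- binding_model(n, kd, ru, rb)
    expect_equal(binding_isotherm(m, a), literal_isotherm(a, kd, ru, rb, n),
                 tolerance = 1e-12)
  }
})

test_that("isotherms are monotone in analyte concentration", {
  a <- seq(0, 400, by = 2)
  up <- binding_isotherm(binding_model(2, 20, 3.5, 7), a)
  down <- binding_isotherm(binding_model(2, 20, 2.3, 0.8), a)
  expect_true(all(diff(up) >= 0))
  expect_true(all(diff(down) <= 0))
})

test_that("noise-free titrations are recovered exactly for both study systems", {
  # ssDNA indicator collapsing on peptide binding
  m_a <- binding_model(2, 5.3, 2.3, 0.8)
  fit_a <- fit_binding(make_titration(m_a), 2)
  expect_equal(fit_a$model$kd_um, 5.3, tolerance = 1e-6)
  expect_equal(fit_a$model$rh_unbound_nm, 2.3, tolerance = 1e-6)
  expect_equal(fit_a$model$rh_bound_nm, 0.8, tolerance = 1e-6)
  expect_lt(fit_a$rss, 1e-12)

  # protein indicator growing on ssDNA binding
  m_b <- binding_model(2, 50.9, 3.5, 7)
  tit_b <- make_titration(m_b, c(0, 2, 5, 10, 20, 40, 70, 110, 160, 220, 284))
  fit_b <- fit_binding(tit_b, 2)
  expect_equal(fit_b$model$kd_um, 50.9, tolerance = 1e-6)

  # fixed unbound radius variant
  fit_fix <- fit_binding(make_titration(m_a), 2, fix_unbound = 2.3)
  expect_equal(fit_fix$model$kd_um, 5.3, tolerance = 1e-6)
  expect_equal(fit_fix$model$rh_unbound_nm, 2.3)

  expect_equal(glance(fit_a)$overall_association, (1 / 5.3)^2,
               tolerance = 1e-6)
})

test_that("underdetermined or malformed titrations are rejected", {
  m <- binding_model(2, 5.3, 2.3, 0.8)
  tiny <- make_titration(m, c(0, 5, 50))
  expect_error(fit_binding(tiny, 2), class = "capflowr_fit_error")
  expect_error(fit_binding(make_titration(m), 4),
               class = "capflowr_validation_error")
})

test_that("noisy replicates recover K_d and its uncertainty honestly", {
  m <- binding_model(2, 5.3, 2.3, 0.8)
  tit0 <- make_titration(m)
  set.seed(77)
  kds <- numeric(30)
  cover <- 0
  for (i in 1:30) {
    tit <- tit0
    tit$rh_nm <- tit$rh_nm * (1 + rnorm(nrow(tit), 0, 0.02))
    fit <- suppressWarnings(fit_binding(tit, 2))
    kds[i] <- fit$model$kd_um
    if (abs(fit$model$kd_um - 5.3) <= 2 * fit$kd_se_um) cover <- cover + 1
  }
  expect_lt(abs(median(kds) - 5.3) / 5.3, 0.10)
  expect_gte(cover / 30, 0.8)
})

test_that("broom methods expose the fit tidily", {
  m <- binding_model(2, 5.3, 2.3, 0.8)
  fit <- fit_binding(make_titration(m), 2)
  td <- tidy(fit)
  expect_equal(td$term, c("kd_um", "rh_unbound_nm", "rh_bound_nm"))
  expect_equal(td$estimate[1], 5.3, tolerance = 1e-6)
  aug <- augment(fit)
  expect_true(all(abs(aug$.resid) < 1e-6))
  expect_s3_class(autoplot(fit), "ggplot")
})
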