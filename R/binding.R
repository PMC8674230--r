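#' Hydrodynamic radius from a Taylorgram
#'
#' Fits a Gaussian to a Taylor-dispersion peak; the temporal variance of
#' the dispersed plug encodes the analyte's diffusivity through
#' `D = r_c^2 * t_R / (24 * sigma_t^2)` (with `r_c = D_cap/2` the capillary
#' inner radius and `t_R` the peak centre), which the Stokes-Einstein
#' relation `R_h = kB * T / (6 * pi * mu * D)` converts to a hydrodynamic
#' radius.
#'
#' @param trace A [cap_trace()] containing a single dominant peak.
#' @param system A [capillary_system()] (radius, viscosity, temperature).
#' @param temperature_k Temperature used in Stokes-Einstein (defaults to
#'   the system temperature).
#' @return One-row tibble: `r_h_nm`, `d_m2_s`, `t_r_s`, `sigma_s`,
#'   `amplitude_fu`.
#' @examples
#' tg <- simulate_taylorgram(2.3, residence_time_s = 120)
#' taylorgram_rh(tg)$r_h_nm # ~2.3
#' @export
taylorgram_rh <- function(trace, system = capillary_system(),
                          temperature_k = system$temperature_k) {
  t <- trace$time_s
  y <- trace$signal_fu
  i0 <- which.max(y)
  a0 <- y[i0]
  c0 <- t[i0]
  above <- y > a0 / 2
  s0 <- max(diff(range(t[above])) / 2.355, 3 * median(diff(t)))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * exp(-(t - c)^2 / (2 * s^2)),
      start = list(a = a0, c = c0, s = s0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    abort("Taylorgram Gaussian fit did not converge.",
          class = "capflowr_fit_error")
  }
  p <- as.list(coef(fit))
  sigma2 <- p$s^2
  if (!is.finite(sigma2) || sigma2 <= 0 || p$c <= 0) {
    abort("Degenerate Taylorgram peak (non-positive width or centre).",
          class = "capflowr_fit_error")
  }
  r_c <- system$inner_diameter_m / 2
  d_diff <- r_c^2 * p$c / (24 * sigma2)
  r_h <- .kB * temperature_k / (6 * pi * system$viscosity_pa_s * d_diff)
  tibble::tibble(r_h_nm = r_h * 1e9, d_m2_s = d_diff, t_r_s = p$c,
                 sigma_s = abs(p$s), amplitude_fu = p$a)
}

#' Cooperative binding model for apparent hydrodynamic radius
#'
#' For an indicator I binding n analyte molecules A with full cooperativity
#' (no partially bound species), the bound fraction at analyte
#' concentration `[A]` is `f_b = ([A]/K_d)^n / (1 + ([A]/K_d)^n)` and the
#' apparent radius is the harmonic mixture
#' `1/R_h = (1 - f_b)/R_unbound + f_b/R_bound` -- algebraically identical
#' to the isotherm written in terms of `(1/K_d)^n * [A]^n`.  The overall
#' association constant of `I + nA <-> IA_n` is `(K_a)^n = [IA_n]/([I][A]^n)`
#' with the reported `K_d = 1/K_a`, the intuitive per-site concentration
#' scale of the transition.  The bound radius may be smaller or larger than
#' the unbound one (binding-induced collapse vs complex growth).
#'
#' @param stoichiometry_n Stoichiometry n in \{1, 2, 3\}.
#' @param kd_um Dissociation constant K_d in uM (> 0).
#' @param rh_unbound_nm,rh_bound_nm Hydrodynamic radii of free and fully
#'   bound indicator, nm (> 0).
#' @return A `binding_model` list.
#' @export
binding_model <- function(stoichiometry_n, kd_um, rh_unbound_nm,
                          rh_bound_nm) {
  if (!stoichiometry_n %in% 1:3) {
    abort("stoichiometry_n must be 1, 2 or 3.",
          class = "capflowr_validation_error")
  }
  if (kd_um <= 0 || rh_unbound_nm <= 0 || rh_bound_nm <= 0) {
    abort("K_d and radii must be strictly positive.",
          class = "capflowr_validation_error")
  }
  structure(list(stoichiometry_n = as.integer(stoichiometry_n),
                 kd_um = kd_um, rh_unbound_nm = rh_unbound_nm,
                 rh_bound_nm = rh_bound_nm),
            class = "binding_model")
}

#' @rdname binding_model
#' @param model A `binding_model`.
#' @param analyte_um Analyte concentrations in uM (>= 0).
#' @return `binding_isotherm()`: apparent R_h in nm at each concentration.
#' @export
binding_isotherm <- function(model, analyte_um) {
  stopifnot(all(analyte_um >= 0))
  isotherm_rh(analyte_um, model$kd_um, model$rh_unbound_nm,
              model$rh_bound_nm, model$stoichiometry_n)
}

isotherm_rh <- function(a_um, kd_um, ru_nm, rb_nm, n) {
  x <- (a_um / kd_um)^n
  fb <- x / (1 + x)
  1 / ((1 - fb) / ru_nm + fb / rb_nm)
}

#' Fit a cooperative binding isotherm to a titration
#'
#' Nonlinear least squares over `(K_d, R_unbound, R_bound)` for a fixed
#' stoichiometry, fitted in `log10(K_d)` with positivity bounds on the
#' radii.  Starting values come from the data: the unbound radius from the
#' lowest-concentration point, the bound radius from the highest, and K_d
#' from the concentration nearest the mid-transition radius.  Standard
#' errors are taken from the Jacobian at the optimum (delta method for
#' K_d).  A K_d estimate more than 10x outside the titrated range raises an
#' extrapolation warning.
#'
#' @param titration Data frame with columns `analyte_um`, `rh_nm` and
#'   optionally `rh_sd_nm` (per-point SDs used as `1/sd^2` weights).  The
#'   zero-analyte point is permitted and informative for the unbound
#'   radius.
#' @param stoichiometry_n Stoichiometry in \{1, 2, 3\}.
#' @param fix_unbound Optional fixed unbound radius in nm.
#' @param weighted Use `1/rh_sd_nm^2` weights when the column is present.
#' @return A `cap_binding_fit`: the fitted [binding_model()], standard
#'   errors, residual sum of squares, and the data.  Supports [tidy()],
#'   [glance()], [augment()] and [autoplot()].
#' @examples
#' truth <- binding_model(2, 5.3, 2.3, 0.8)
#' tit <- tibble::tibble(analyte_um = c(0, 1, 2, 4, 6, 10, 20, 50, 100, 360),
#'                       rh_nm = binding_isotherm(truth, analyte_um))
#' fit <- fit_binding(tit, stoichiometry_n = 2)
#' tidy(fit)
#' @export
fit_binding <- function(titration, stoichiometry_n, fix_unbound = NULL,
                        weighted = FALSE) {
  stopifnot(all(c("analyte_um", "rh_nm") %in% names(titration)))
  n_par <- if (is.null(fix_unbound)) 3L else 2L
  if (nrow(titration) <= n_par) {
    abort(sprintf("Underdetermined: %d titration points for %d parameters.",
                  nrow(titration), n_par),
          class = "capflowr_fit_error")
  }
  if (!stoichiometry_n %in% 1:3) {
    abort("stoichiometry_n must be 1, 2 or 3.",
          class = "capflowr_validation_error")
  }
  a <- titration$analyte_um
  rh <- titration$rh_nm
  w <- if (weighted && "rh_sd_nm" %in% names(titration)) {
    1 / titration$rh_sd_nm^2
  } else {
    rep(1, length(a))
  }
  ru0 <- rh[which.min(a)]
  rb0 <- rh[which.max(a)]
  mid <- (ru0 + rb0) / 2
  pos <- a > 0
  kd0 <- a[pos][which.min(abs(rh[pos] - mid))]
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- median(a[pos])
  df <- data.frame(a = a, rh = rh)
  nn <- stoichiometry_n
  fit <- if (is.null(fix_unbound)) {
    minpack.lm::nlsLM(
      rh ~ isotherm_rh(a, 10^logkd, ru, rb, nn),
      data = df, weights = w,
      start = list(logkd = log10(kd0), ru = ru0, rb = rb0),
      lower = c(-12, 1e-6, 1e-6), upper = c(12, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)
    )
  } else {
    ru_fix <- fix_unbound
    minpack.lm::nlsLM(
      rh ~ isotherm_rh(a, 10^logkd, ru_fix, rb, nn),
      data = df, weights = w,
      start = list(logkd = log10(kd0), rb = rb0),
      lower = c(-12, 1e-6), upper = c(12, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)
    )
  }
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) {
    rep(NA_real_, length(est))
  })
  kd <- 10^est[["logkd"]]
  kd_se <- kd * log(10) * se[["logkd"]] # delta method
  ru <- if (is.null(fix_unbound)) est[["ru"]] else fix_unbound
  ru_se <- if (is.null(fix_unbound)) se[["ru"]] else 0
  rb <- est[["rb"]]
  rb_se <- se[["rb"]]
  pos_a <- a[a > 0]
  extrapolated <- length(pos_a) > 0 &&
    (kd < min(pos_a) / 10 || kd > max(pos_a) * 10)
  if (extrapolated) {
    warn(sprintf("K_d estimate (%.3g uM) lies more than 10x outside the titrated range.",
                 kd))
  }
  model <- binding_model(stoichiometry_n, kd, ru, rb)
  structure(
    list(model = model,
         kd_se_um = kd_se, rh_unbound_se_nm = ru_se, rh_bound_se_nm = rb_se,
         overall_association = (1 / kd)^stoichiometry_n,
         rss = sum(w * (rh - binding_isotherm(model, a))^2),
         n = length(a), weighted = weighted,
         fixed_unbound = !is.null(fix_unbound),
         extrapolated = extrapolated,
         data = tibble::as_tibble(titration)),
    class = "cap_binding_fit"
  )
}

#' Compare candidate stoichiometries on one titration
#'
#' Fits the 1:1, 1:2 and 1:3 models (or any subset) and reports each fit's
#' residual sum of squares; the lowest-RSS model is the selected
#' stoichiometry.
#'
#' @inheritParams fit_binding
#' @param stoichiometries Integer vector of candidate n values.
#' @return A tibble with one row per candidate (`stoichiometry_n`, `kd_um`,
#'   `rss`, `selected`), ordered as given.
#' @export
compare_binding_models <- function(titration, stoichiometries = 1:3,
                                   fix_unbound = NULL) {
  fits <- purrr::map(stoichiometries, function(n) {
    tryCatch(suppressWarnings(fit_binding(titration, n, fix_unbound)),
             error = function(e) NULL)
  })
  rss <- purrr::map_dbl(fits, ~ if (is.null(.x)) Inf else .x$rss)
  tibble::tibble(
    stoichiometry_n = as.integer(stoichiometries),
    kd_um = purrr::map_dbl(fits, ~ if (is.null(.x)) NA_real_ else .x$model$kd_um),
    rss = rss,
    selected = rss == min(rss)
  )
}

#' @export
print.cap_binding_fit <- function(x, ...) {
  m <- x$model
  cat(sprintf(
    "<cap_binding_fit> 1:%d model: K_d = %.4g +/- %.2g uM, R_h %.3g -> %.3g nm (RSS %.3g, n=%d)\n",
    m$stoichiometry_n, m$kd_um, x$kd_se_um, m$rh_unbound_nm, m$rh_bound_nm,
    x$rss, x$n))
  invisible(x)
}

#' @method tidy cap_binding_fit
#' @export
tidy.cap_binding_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kd_um", "rh_unbound_nm", "rh_bound_nm"),
    estimate = c(x$model$kd_um, x$model$rh_unbound_nm, x$model$rh_bound_nm),
    std.error = c(x$kd_se_um, x$rh_unbound_se_nm, x$rh_bound_se_nm)
  )
}

#' @method glance cap_binding_fit
#' @export
glance.cap_binding_fit <- function(x, ...) {
  tibble::tibble(stoichiometry_n = x$model$stoichiometry_n,
                 kd_um = x$model$kd_um, rss = x$rss, nobs = x$n,
                 overall_association = x$overall_association,
                 extrapolated = x$extrapolated)
}

#' @method augment cap_binding_fit
#' @export
augment.cap_binding_fit <- function(x, ...) {
  dplyr::mutate(x$data,
                .fitted = binding_isotherm(x$model, .data$analyte_um),
                .resid = .data$rh_nm - .fitted)
}
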