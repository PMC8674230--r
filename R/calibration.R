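#' Fit a standard curve relating concentration to baseline fluorescence
#'
#' The dilute-phase readout is calibrated by injecting a series of known,
#' non-phase-separated concentrations of the labeled species and recording
#' the flat baseline each produces.  The calibration is an ordinary
#' least-squares line `baseline_fu = slope * conc_um + intercept`; inverse
#' prediction converts a measured baseline back to a dilute-phase
#' concentration.  A non-positive fitted slope is an error: it signals
#' phase-separated standards or mislabeled data, not a usable calibration.
#'
#' @param concentrations_um Known concentrations in uM (>= 2 distinct).
#' @param baselines_fu Measured baseline fluorescence, FU.
#' @return A `cap_calibration` object with fields `slope`, `intercept`,
#'   `r_squared` and the calibration table; supports [predict()], [tidy()]
#'   and [invert_calibration()].
#' @examples
#' cal <- fit_standard_curve(c(10, 20, 50), c(1, 2, 5))
#' cal$slope                       # 0.1 FU/uM
#' invert_calibration(cal, 3.5)    # 35 uM
#' @export
fit_standard_curve <- function(concentrations_um, baselines_fu) {
  if (length(concentrations_um) != length(baselines_fu)) {
    abort("Concentration and baseline vectors must have equal length.",
          class = "capflowr_validation_error")
  }
  if (length(unique(concentrations_um)) < 2) {
    abort("At least 2 distinct concentrations are required for calibration.",
          class = "capflowr_calibration_error")
  }
  fit <- lm(baselines_fu ~ concentrations_um)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    abort("Calibration slope is not positive; standards may be phase separated or mislabeled.",
          class = "capflowr_calibration_error")
  }
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((baselines_fu - mean(baselines_fu))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(
      slope = slope,
      intercept = unname(coef(fit)[1]),
      r_squared = r2,
      slope_se = suppressWarnings(summary(fit)$coefficients[2, 2]),
      data = tibble::tibble(conc_um = concentrations_um,
                            baseline_fu = baselines_fu)
    ),
    class = "cap_calibration"
  )
}

#' Predict baseline fluorescence from concentration
#'
#' @param object A `cap_calibration`.
#' @param conc_um Concentrations in uM.
#' @param ... Unused.
#' @return Predicted baseline FU.
#' @export
predict.cap_calibration <- function(object, conc_um, ...) {
  object$intercept + object$slope * conc_um
}

#' Invert a calibration: concentration from baseline fluorescence
#'
#' @param calibration A `cap_calibration`.
#' @param baseline_fu Baseline fluorescence, FU.
#' @return Concentration in uM.
#' @export
invert_calibration <- function(calibration, baseline_fu) {
  (baseline_fu - calibration$intercept) / calibration$slope
}

#' @export
print.cap_calibration <- function(x, ...) {
  cat(sprintf("<cap_calibration> slope=%.6g FU/uM, intercept=%.6g FU, R^2=%.4f, n=%d\n",
              x$slope, x$intercept, x$r_squared, nrow(x$data)))
  invisible(x)
}

#' @method tidy cap_calibration
#' @export
tidy.cap_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$slope_se)
  )
}

#' @method glance cap_calibration
#' @export
glance.cap_calibration <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = nrow(x$data))
}
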