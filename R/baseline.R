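#' Fit a four-parameter logistic to the front of a trace
#'
#' The injected solution front produces a sigmoidal signal rise as the
#' centreline fluid reaches the detector first.  The front is modelled as a
#' 4-parameter logistic
#' `y(t) = lower + (upper - lower) / (1 + exp(-rate * (t - midpoint)))`,
#' initialized from data quantiles (lower = 2% quantile, upper = 98%
#' quantile, midpoint = first half-range crossing, rate from the 25-75%
#' rise time) and refined by Levenberg-Marquardt least squares.
#'
#' @param trace A [cap_trace()].
#' @return A list with `lower`, `upper`, `midpoint`, `rate`, `fitted`.
#' @keywords internal
fit_front_sigmoid <- function(trace) {
  t <- trace$time_s
  y <- trace$signal_fu
  lo0 <- unname(quantile(y, 0.02, type = 7))
  hi0 <- unname(quantile(y, 0.98, type = 7))
  if (hi0 <= lo0) {
    abort("Front detection failed: trace has no signal rise.",
          class = "capflowr_front_error")
  }
  half <- lo0 + 0.5 * (hi0 - lo0)
  mid0 <- t[which(y >= half)[1]]
  q25 <- t[which(y >= lo0 + 0.25 * (hi0 - lo0))[1]]
  q75 <- t[which(y >= lo0 + 0.75 * (hi0 - lo0))[1]]
  rise <- max(q75 - q25, trace_dt(trace, require_uniform = FALSE))
  rate0 <- 2.2 / rise # logit(0.75) - logit(0.25) = ~2.2
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ lower + (upper - lower) / (1 + exp(-rate * (t - midpoint))),
      start = list(lower = lo0, upper = hi0, midpoint = mid0, rate = rate0),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10,
                                           ptol = 1e-10)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    abort("Front detection failed: logistic fit did not converge.",
          class = "capflowr_front_error")
  }
  p <- as.list(coef(fit))
  if (p$upper <= p$lower) {
    abort("Front detection failed: upper asymptote not above lower.",
          class = "capflowr_front_error")
  }
  p$fitted <- p$lower + (p$upper - p$lower) /
    (1 + exp(-p$rate * (t - p$midpoint)))
  p
}

#' Extract the dilute-phase baseline from a trace
#'
#' Implements the automated baseline recipe for capillary-flow LLPS traces:
#'
#' 1. Discard samples larger than 1.10 x the expected signal (the
#'    calibration prediction at the known total concentration) -- this
#'    removes droplet spikes and saturated stretches.
#' 2. Median-filter the surviving samples with a 31-point window (a count of
#'    data points, not a duration, so the trace must be uniformly sampled).
#' 3. Fit a 4-parameter logistic to the smoothed series; the baseline
#'    region starts where the fit first exceeds 99% of its upper asymptote.
#' 4. The baseline fluorescence is the lower 5% quantile (type-7) of the
#'    smoothed series within that region, converted to a dilute-phase
#'    concentration by inverse calibration.
#'
#' Smoothing before the sigmoid fit keeps the front location robust to
#' dense spike trains; peak detection ([detect_peaks()]) still runs on the
#' raw trace.
#'
#' @param trace A [cap_trace()] spanning the front with at least
#'   `median_window` post-front samples.
#' @param calibration A [fit_standard_curve()] result.
#' @param expected_total_conc_um Total (nominal) concentration of the sample
#'   in uM; sets the +10% discard level.
#' @param median_window Median filter window in samples (odd; default 31).
#' @param quantile_p Lower quantile defining the baseline (default 0.05).
#' @return A `cap_baseline` list: `baseline_fu`, `dilute_conc_um`,
#'   `front_time_s` (front midpoint), `region_start_s`, `region_end_s`,
#'   `sigmoid` (4PL parameters), `n_region`, `n_used`.
#' @examples
#' cal <- fit_standard_curve(c(10, 20, 50), c(0.5, 1.0, 2.5))
#' cfg <- simulation_config(ground_truth = synthetic_ground_truth(
#'   total_conc_um = 100, dilute_conc_um = 70, droplet_count = 20, seed = 1))
#' sim <- simulate_trace(cfg)
#' extract_baseline(sim$trace, cal, expected_total_conc_um = 100)
#' @export
extract_baseline <- function(trace, calibration, expected_total_conc_um,
                             median_window = 31, quantile_p = 0.05) {
  stopifnot(inherits(trace, "cap_trace"))
  trace_dt(trace) # enforce uniform sampling
  expected_fu <- predict(calibration, expected_total_conc_um)
  keep <- trace$signal_fu <= 1.10 * expected_fu
  if (sum(keep) < median_window) {
    abort(sprintf("Insufficient data: %d samples survive the +10%% discard (need >= %d).",
                  sum(keep), median_window),
          class = "capflowr_insufficient_data_error")
  }
  t_kept <- trace$time_s[keep]
  smoothed <- runmed(trace$signal_fu[keep], k = median_window,
                     endrule = "median")
  sig <- fit_front_sigmoid(cap_trace(t_kept, smoothed))
  idx <- which(sig$fitted >= 0.99 * sig$upper)
  if (length(idx) == 0) {
    abort("Front detection failed: fit never reaches 99% of its upper asymptote.",
          class = "capflowr_front_error")
  }
  region <- seq(idx[1], length(smoothed))
  if (length(region) < median_window) {
    abort(sprintf("Insufficient baseline data: %d post-front samples (need >= %d).",
                  length(region), median_window),
          class = "capflowr_insufficient_data_error")
  }
  baseline_fu <- unname(quantile(smoothed[region], quantile_p, type = 7))
  structure(
    list(
      baseline_fu = baseline_fu,
      dilute_conc_um = invert_calibration(calibration, baseline_fu),
      front_time_s = sig$midpoint,
      region_start_s = t_kept[region[1]],
      region_end_s = t_kept[length(smoothed)],
      sigmoid = sig[c("lower", "upper", "midpoint", "rate")],
      n_region = length(region),
      n_used = sum(keep),
      expected_fu = expected_fu,
      median_window = median_window,
      quantile_p = quantile_p
    ),
    class = "cap_baseline"
  )
}

#' @export
print.cap_baseline <- function(x, ...) {
  cat(sprintf(
    "<cap_baseline> baseline=%.4g FU -> dilute phase %.4g uM; region [%.3g, %.3g] s (front at %.3g s)\n",
    x$baseline_fu, x$dilute_conc_um, x$region_start_s, x$region_end_s,
    x$front_time_s))
  invisible(x)
}

#' @method glance cap_baseline
#' @export
glance.cap_baseline <- function(x, ...) {
  tibble::tibble(
    baseline_fu = x$baseline_fu,
    dilute_conc_um = x$dilute_conc_um,
    front_time_s = x$front_time_s,
    region_start_s = x$region_start_s,
    n_used = x$n_used
  )
}
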