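#' Detect droplet spikes above a fixed baseline
#'
#' Each droplet passing the detector rides on the dilute-phase baseline as a
#' signal spike.  Peaks are local maxima inside the baseline region whose
#' signal exceeds `baseline_fu + threshold_fu`; the threshold is an absolute
#' offset in FU (default 0.2 FU above the baseline).  Each contiguous
#' supra-threshold region yields one peak: its height is the region maximum
#' minus the baseline, its time the location of that maximum (for a
#' plateaued, e.g. saturated, maximum the first sample of the plateau), and
#' its integral the trapezoidal area above the baseline between the
#' surrounding threshold crossings.  A peak whose raw maximum reaches the
#' detector ceiling is flagged as saturated.
#'
#' @param trace A [cap_trace()].
#' @param baseline A [extract_baseline()] result, or a single numeric
#'   baseline level in FU (analyzed region then spans the whole trace).
#' @param threshold_fu Peak threshold in FU above the baseline.
#' @param saturation_ceiling_fu Detector ceiling in FU (default 50).
#' @return A `cap_peaks` tibble with columns `peak_time_s`, `height_fu`,
#'   `integral_fu_s`, `saturated`; attributes `threshold_used`,
#'   `baseline_fu`, `saturation_ceiling`.  Empty when no peaks are found.
#' @export
detect_peaks <- function(trace, baseline, threshold_fu = 0.2,
                         saturation_ceiling_fu = 50) {
  stopifnot(inherits(trace, "cap_trace"))
  if (inherits(baseline, "cap_baseline")) {
    base_fu <- baseline$baseline_fu
    in_region <- trace$time_s >= baseline$region_start_s
  } else {
    base_fu <- as.numeric(baseline)
    stopifnot(length(base_fu) == 1)
    in_region <- rep(TRUE, nrow(trace))
  }
  t <- trace$time_s[in_region]
  y <- trace$signal_fu[in_region]
  runs <- contiguous_runs(y > base_fu + threshold_fu)
  peaks <- purrr::map_dfr(runs, function(r) {
    seg <- seq(r[1], r[2])
    i_max <- seg[which.max(y[seg])] # which.max: first index of a plateau
    tibble::tibble(
      peak_time_s = t[i_max],
      height_fu = y[i_max] - base_fu,
      integral_fu_s = segment_area_above(t, y, r[1], r[2], base_fu),
      saturated = y[i_max] >= saturation_ceiling_fu
    )
  })
  if (nrow(peaks) == 0) {
    peaks <- tibble::tibble(peak_time_s = numeric(0), height_fu = numeric(0),
                            integral_fu_s = numeric(0), saturated = logical(0))
  }
  new_cap_peaks(peaks, threshold_used = threshold_fu, baseline_fu = base_fu,
                saturation_ceiling = saturation_ceiling_fu)
}

new_cap_peaks <- function(df, threshold_used, baseline_fu = NA_real_,
                          saturation_ceiling = NA_real_) {
  attr(df, "threshold_used") <- threshold_used
  attr(df, "baseline_fu") <- baseline_fu
  attr(df, "saturation_ceiling") <- saturation_ceiling
  class(df) <- unique(c("cap_peaks", class(df)))
  df
}

# start/end index pairs of TRUE runs in a logical vector
contiguous_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  purrr::map2(starts[r$values], ends[r$values], c)
}

# area of (y - base) over samples i1..i2: one sampling interval of support
# per sample, which equals the trapezoid of the piecewise-linear trace
# extended down to the baseline over the flanking half-intervals
segment_area_above <- function(t, y, i1, i2, base) {
  dt <- if (length(t) > 1) median(diff(t)) else 0
  sum(pmax(y[seq(i1, i2)] - base, 0)) * dt
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Amount of protein partitioned into droplets
#'
#' Total minus dilute-phase concentration, in dilute-phase-equivalent uM.
#' The value may come out slightly negative from measurement noise; it is
#' reported as-is, with `within_noise` flagging magnitudes at or below the
#' stated noise bound.
#'
#' @param total_conc_um Total protein concentration, uM.
#' @param dilute_conc_um Measured dilute-phase concentration, uM.
#' @param noise_bound_um Concentration noise bound in uM (default 7).
#' @return One-row tibble: `partitioned_um`, `within_noise`.
#' @export
partitioned_amount <- function(total_conc_um, dilute_conc_um,
                               noise_bound_um = 7) {
  stopifnot(total_conc_um >= 0, dilute_conc_um >= 0)
  value <- total_conc_um - dilute_conc_um
  tibble::tibble(partitioned_um = value,
                 within_noise = abs(value) <= noise_bound_um)
}

#' Check droplet reversibility between two measurements
#'
#' Compares spike counts before and after a perturbation expected to
#' dissolve liquid droplets (e.g. dilution below the critical concentration
#' or heating above the cloud point).  The system is called reversible when
#' at least `min_fraction_lost` of the spikes disappear.  Irreversible spike
#' persistence indicates maturation, e.g. a liquid-to-solid transition.
#'
#' @param before,after `cap_peaks` tables from same-channel analyses.
#' @param min_fraction_lost Fraction of spikes that must vanish (default 0.95).
#' @return One-row tibble: `reversible`, `n_before`, `n_after`,
#'   `fraction_lost`.
#' @export
reversibility_check <- function(before, after, min_fraction_lost = 0.95) {
  n_before <- nrow(before)
  n_after <- nrow(after)
  if (n_before == 0) {
    abort("Reversibility is undefined with zero peaks before perturbation.",
          class = "capflowr_validation_error")
  }
  tibble::tibble(
    reversible = n_after <= (1 - min_fraction_lost) * n_before,
    n_before = n_before,
    n_after = n_after,
    fraction_lost = 1 - n_after / n_before,
    baseline_shift_fu = (attr(after, "baseline_fu") %||% NA_real_) -
      (attr(before, "baseline_fu") %||% NA_real_)
  )
}
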