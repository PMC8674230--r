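#' Fraction of a trace's signal carried by droplet spikes
#'
#' Contiguous regions where the signal exceeds the baseline by more than
#' `rel_threshold` (default 0.5%) of the local baseline value are counted
#' as peaks; the ratio is the summed above-baseline peak area divided by
#' the total area under the trace over the analyzed region (trapezoidal
#' quadrature on the native time grid).  With a small labeled spike-in,
#' this ratio is the fraction of the label found inside droplets, so it is
#' invariant to uniform rescaling of the trace.
#'
#' @param trace A [cap_trace()].
#' @param baseline A [extract_baseline()] result (analyzed region = its
#'   baseline region), an [als_baseline()] tibble on the trace grid, a
#'   numeric vector on the trace grid, or a single baseline level.
#' @param rel_threshold Relative peak criterion (default 0.005).
#' @return One-row tibble: `ratio`, `peak_area_fu_s`, `curve_area_fu_s`,
#'   `n_peak_regions`.
#' @export
signal_ratio <- function(trace, baseline, rel_threshold = 0.005) {
  if (inherits(baseline, "cap_baseline")) {
    in_region <- trace$time_s >= baseline$region_start_s
    z <- rep(baseline$baseline_fu, sum(in_region))
  } else if (is.data.frame(baseline)) {
    in_region <- rep(TRUE, nrow(trace))
    z <- baseline$baseline_fu
  } else if (length(baseline) == 1) {
    in_region <- rep(TRUE, nrow(trace))
    z <- rep(as.numeric(baseline), nrow(trace))
  } else {
    in_region <- rep(TRUE, nrow(trace))
    z <- as.numeric(baseline)
  }
  t <- trace$time_s[in_region]
  y <- trace$signal_fu[in_region]
  if (length(z) != length(y)) {
    abort("Baseline must cover the analyzed region.",
          class = "capflowr_validation_error")
  }
  if (any(z <= 0)) {
    abort("Relative peak criterion undefined: baseline is not strictly positive.",
          class = "capflowr_validation_error")
  }
  curve_area <- trapz(t, y)
  if (curve_area <= 0) {
    abort("Degenerate trace: zero curve area in the analyzed region.",
          class = "capflowr_validation_error")
  }
  runs <- contiguous_runs((y - z) / z > rel_threshold)
  dt_med <- if (length(t) > 1) median(diff(t)) else 0
  # one sampling interval of support per supra-threshold sample (trapezoid
  # of the trace extended to the baseline over the flanking half-intervals)
  peak_area <- sum(purrr::map_dbl(runs, function(r) {
    seg <- seq(r[1], r[2])
    sum(y[seg] - z[seg]) * dt_med
  }))
  tibble::tibble(ratio = peak_area / curve_area,
                 peak_area_fu_s = peak_area,
                 curve_area_fu_s = curve_area,
                 n_peak_regions = length(runs))
}

#' Relative enrichment of one labeled species over another in droplets
#'
#' Two samples of identical composition are measured, differing only in
#' which species carries the fluorescent label.  The droplet-phase signal
#' fraction ([signal_ratio()]) of each is computed and their quotient is
#' the relative enrichment factor of species A over species B inside the
#' droplets.  Because both numerator and denominator are fractions of their
#' own label, the dense-phase volume fraction cancels and never needs to be
#' known.
#'
#' @param trace_a,trace_b Traces of the A-labeled and B-labeled samples.
#' @param baseline_a,baseline_b Baselines for each trace (any form accepted
#'   by [signal_ratio()]).
#' @param rel_threshold Relative peak criterion (default 0.005).
#' @return One-row tibble: `enrichment`, `ratio_a`, `ratio_b`.
#' @export
relative_enrichment <- function(trace_a, trace_b, baseline_a, baseline_b,
                                rel_threshold = 0.005) {
  ra <- signal_ratio(trace_a, baseline_a, rel_threshold)
  rb <- signal_ratio(trace_b, baseline_b, rel_threshold)
  if (rb$ratio == 0) {
    abort("Species B has zero droplet-phase signal; relative enrichment undefined (no spikes detected in trace B).",
          class = "capflowr_validation_error")
  }
  tibble::tibble(enrichment = ra$ratio / rb$ratio,
                 ratio_a = ra$ratio, ratio_b = rb$ratio)
}

#' Photobleaching-corrected FRAP normalization
#'
#' Normalized recovery intensity `(I_t - I_b) / r` with the photobleaching
#' rate `r = I_c / I_c0`, where `I_c0` and `I_c` are a control region's
#' intensity before and after photobleaching, `I_t` the bleached region's
#' intensity and `I_b` the background.
#'
#' @param i_t Intensity of the bleached region at time t.
#' @param i_b Background intensity.
#' @param i_c Control-region intensity after photobleaching (> 0).
#' @param i_c0 Control-region intensity before photobleaching (> 0).
#' @return Normalized intensity (dimensionless).
#' @export
frap_normalize <- function(i_t, i_b, i_c, i_c0) {
  if (any(i_c0 <= 0) || any(i_c <= 0)) {
    abort("Control intensities must be strictly positive.",
          class = "capflowr_domain_error")
  }
  (i_t - i_b) / (i_c / i_c0)
}

#' Instrument throughput
#'
#' Samples analyzed per hour, `r = N / t`.
#'
#' @param n_samples Number of samples run.
#' @param elapsed_h Elapsed time in hours (> 0).
#' @return Samples per hour.
#' @examples
#' throughput(15, 3.6) # ~4 samples/h
#' @export
throughput <- function(n_samples, elapsed_h) {
  if (elapsed_h <= 0) {
    abort("elapsed_h must be positive.", class = "capflowr_validation_error")
  }
  n_samples / elapsed_h
}

#' Dense-phase mass fraction of one component
#'
#' Helper for coacervate stoichiometry: the mass fraction of component A
#' among (A, B) given molar amounts and explicit molecular weights.  No
#' default molecular weights are assumed.
#'
#' @param conc_a_um,conc_b_um Molar concentrations, uM.
#' @param mw_a_da,mw_b_da Molecular weights, Da.
#' @return Mass fraction of A, in `[0, 1]`.
#' @export
mass_fraction <- function(conc_a_um, conc_b_um, mw_a_da, mw_b_da) {
  stopifnot(mw_a_da > 0, mw_b_da > 0, conc_a_um >= 0, conc_b_um >= 0)
  ma <- conc_a_um * mw_a_da
  ma / (ma + conc_b_um * mw_b_da)
}
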