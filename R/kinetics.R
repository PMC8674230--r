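#' Asymmetric least squares (ALS) baseline
#'
#' Eilers-style asymmetric penalized least squares baseline for a
#' continuously recorded kinetics trace: minimize
#' `sum(w_i * (y_i - z_i)^2) + lambda * sum((diff(z, differences = 2))^2)`
#' with `lambda = 10^smoothness_log10` and asymmetric weights `p` for
#' points above the current baseline and `1 - p` below.  Weights are
#' re-estimated for up to `iterations` passes or until the maximum relative
#' change of the baseline drops below `conv_tol`.  Because `p` is tiny,
#' upward droplet spikes are left out of the baseline while the smooth
#' signal drift is followed.
#'
#' The banded penalized system is solved sparsely (second-difference
#' penalty, order 2).
#'
#' @param trace A uniformly sampled [cap_trace()] with at least 10 samples.
#' @param asymmetry_p Asymmetry weight p (default 0.001).
#' @param smoothness_log10 log10 of the smoothness penalty lambda
#'   (default 4).
#' @param iterations Maximum re-weighting passes (default 20).
#' @param conv_tol Convergence tolerance on the maximum relative baseline
#'   change between passes (default 0.005).
#' @param keep_iterations Also return the baseline after every pass.
#' @return A tibble `time_s`, `baseline_fu` (attribute `iterations_run`;
#'   with `keep_iterations`, attribute `iterates` is a list of baselines).
#' @export
als_baseline <- function(trace, asymmetry_p = 0.001, smoothness_log10 = 4,
                         iterations = 20, conv_tol = 0.005,
                         keep_iterations = FALSE) {
  stopifnot(inherits(trace, "cap_trace"))
  y <- trace$signal_fu
  n <- length(y)
  if (n < 10) {
    abort("ALS baseline needs at least 10 samples.",
          class = "capflowr_insufficient_data_error")
  }
  trace_dt(trace) # uniform sampling required
  lambda <- 10^smoothness_log10
  d2 <- Matrix::bandSparse(n - 2, n, k = 0:2,
                           diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                            rep(1, n - 2)))
  penalty <- lambda * Matrix::crossprod(d2)
  w <- rep(1, n)
  z <- y
  iterates <- if (keep_iterations) vector("list", iterations) else NULL
  it_run <- 0L
  for (it in seq_len(iterations)) {
    a <- penalty + Matrix::Diagonal(n, w)
    z_new <- as.numeric(Matrix::solve(a, w * y))
    it_run <- it
    if (keep_iterations) iterates[[it]] <- z_new
    rel_change <- max(abs(z_new - z) / pmax(abs(z), 1e-12))
    conv <- it > 1 && rel_change < conv_tol
    z <- z_new
    w <- ifelse(y > z, asymmetry_p, 1 - asymmetry_p)
    if (conv) break
  }
  out <- tibble::tibble(time_s = trace$time_s, baseline_fu = z)
  attr(out, "iterations_run") <- it_run
  if (keep_iterations) attr(out, "iterates") <- iterates[seq_len(it_run)]
  out
}

#' Detect droplet peaks against a drifting baseline (relative criterion)
#'
#' For kinetics traces the peak criterion is relative: a local maximum whose
#' signal exceeds the baseline by more than `rel_threshold` (default 1%) of
#' the local baseline value counts as a droplet.  Each contiguous
#' supra-criterion region yields one peak at its maximum.
#'
#' @param trace A [cap_trace()].
#' @param baseline An [als_baseline()] result on the same time grid (or a
#'   numeric vector of baseline values).
#' @param rel_threshold Relative excess over the baseline (default 0.01).
#' @return A `cap_peaks` tibble (`peak_time_s`, `height_fu`); heights are
#'   signal minus local baseline.
#' @export
detect_kinetic_peaks <- function(trace, baseline, rel_threshold = 0.01) {
  z <- if (is.data.frame(baseline)) baseline$baseline_fu else as.numeric(baseline)
  if (length(z) != nrow(trace)) {
    abort("Baseline must be on the same grid as the trace.",
          class = "capflowr_validation_error")
  }
  if (any(z <= 0)) {
    abort("Relative peak criterion undefined: baseline is not strictly positive.",
          class = "capflowr_validation_error")
  }
  y <- trace$signal_fu
  t <- trace$time_s
  excess <- (y - z) / z
  runs <- contiguous_runs(excess > rel_threshold)
  peaks <- purrr::map_dfr(runs, function(r) {
    seg <- seq(r[1], r[2])
    i_max <- seg[which.max(y[seg] - z[seg])]
    tibble::tibble(peak_time_s = t[i_max], height_fu = y[i_max] - z[i_max])
  })
  if (nrow(peaks) == 0) {
    peaks <- tibble::tibble(peak_time_s = numeric(0), height_fu = numeric(0))
  }
  peaks$integral_fu_s <- NA_real_
  peaks$saturated <- NA
  new_cap_peaks(peaks, threshold_used = rel_threshold)
}

#' Sliding-window average of peak intensities
#'
#' Rolling mean over each consecutive window of `window` peak heights
#' (ordered by time), timestamped at the window's median peak time.  This
#' turns the irregular droplet-event series into a droplet-growth curve.
#'
#' @param peaks A `cap_peaks` tibble.
#' @param window Window length in peaks (default 10).
#' @return A tibble `time_s`, `mean_height_fu`; empty (with a warning) when
#'   there are fewer peaks than `window`.
#' @export
sliding_peak_average <- function(peaks, window = 10) {
  ord <- order(peaks$peak_time_s)
  h <- peaks$height_fu[ord]
  t <- peaks$peak_time_s[ord]
  n <- length(h)
  if (n < window) {
    warn(sprintf("Fewer peaks (%d) than the averaging window (%d); empty series.",
                 n, window))
    return(tibble::tibble(time_s = numeric(0), mean_height_fu = numeric(0)))
  }
  starts <- seq_len(n - window + 1)
  tibble::tibble(
    time_s = purrr::map_dbl(starts, ~ median(t[.x:(.x + window - 1)])),
    mean_height_fu = purrr::map_dbl(starts, ~ mean(h[.x:(.x + window - 1)]))
  )
}

#' Droplet-formation onset and early growth rate
#'
#' The lag time is the time of the first detected droplet peak (for
#' immediate phase separation it approaches the instrument dead time).  The
#' early growth rate is the ordinary least-squares slope of the
#' sliding-window peak-intensity curve over `[fit_start_s, fit_end_s]`
#' (default the first 2 minutes), reported in FU/min.
#'
#' @param peaks A `cap_peaks` tibble from [detect_kinetic_peaks()].
#' @param window Averaging window passed to [sliding_peak_average()].
#' @param fit_start_s,fit_end_s Fit interval in seconds (defaults 0 and 120).
#' @return One-row tibble: `lag_time_s`, `rate_fu_per_min`, `n_peaks`,
#'   `n_fit`, `no_peaks` flag.
#' @export
onset_and_rate <- function(peaks, window = 10, fit_start_s = 0,
                           fit_end_s = 120) {
  if (nrow(peaks) == 0) {
    return(tibble::tibble(lag_time_s = NA_real_, rate_fu_per_min = 0,
                          n_peaks = 0L, n_fit = 0L, no_peaks = TRUE))
  }
  lag <- min(peaks$peak_time_s)
  avg <- suppressWarnings(sliding_peak_average(peaks, window))
  sel <- avg$time_s >= fit_start_s & avg$time_s <= fit_end_s
  n_fit <- sum(sel)
  rate <- if (n_fit >= 2) {
    unname(coef(lm(mean_height_fu ~ time_s, data = avg[sel, ]))[2]) * 60
  } else {
    NA_real_
  }
  tibble::tibble(lag_time_s = lag, rate_fu_per_min = rate,
                 n_peaks = nrow(peaks), n_fit = n_fit, no_peaks = FALSE)
}
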