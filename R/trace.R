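#' Construct a capillary-flow fluorescence trace
#'
#' A trace is one detector channel's time series: time in seconds and signal
#' in (arbitrary) fluorescence units, plus acquisition metadata.  Traces are
#' ordinary tibbles with columns `time_s` and `signal_fu`, carrying the
#' channel label, injection pressure and sample id as attributes, so they
#' compose with dplyr verbs; analysis functions only rely on the two columns.
#'
#' Validation enforces the trace invariants: strictly increasing time, equal
#' column lengths of at least 2, and (for filtering-based analyses)
#' approximately uniform sampling -- the ratio of the largest to the smallest
#' sampling interval must be below 1.5.  Non-monotone time is always an
#' error, never silently sorted.
#'
#' @param time_s Numeric vector of times in seconds, strictly increasing,
#'   non-negative.
#' @param signal_fu Numeric vector of fluorescence, same length as `time_s`.
#'   May dip below zero with noise.
#' @param channel Channel label, e.g. `"alexa488"` or `"tht"`.
#' @param pressure_mbar Injection pressure in mbar (metadata only).
#' @param sample_id Free-text sample identifier.
#' @param metadata Named list of additional key/value metadata.
#' @return A `cap_trace` tibble with columns `time_s`, `signal_fu`.
#' @examples
#' tr <- cap_trace(seq(0, 10, by = 0.1), rnorm(101, 5, 0.05))
#' trace_channel(tr)
#' @export
cap_trace <- function(time_s, signal_fu, channel = "alexa488",
                      pressure_mbar = NA_real_, sample_id = NA_character_,
                      metadata = list()) {
  time_s <- as.numeric(time_s)
  signal_fu <- as.numeric(signal_fu)
  validate_trace_vectors(time_s, signal_fu)
  out <- tibble::tibble(time_s = time_s, signal_fu = signal_fu)
  attr(out, "channel") <- as.character(channel)
  attr(out, "pressure_mbar") <- as.numeric(pressure_mbar)
  attr(out, "sample_id") <- as.character(sample_id)
  attr(out, "metadata") <- metadata
  class(out) <- c("cap_trace", class(out))
  out
}

validate_trace_vectors <- function(time_s, signal_fu) {
  if (length(time_s) != length(signal_fu)) {
    abort("`time_s` and `signal_fu` must have equal length.",
          class = "capflowr_validation_error")
  }
  if (length(time_s) < 2) {
    abort("A trace needs at least 2 samples.",
          class = "capflowr_validation_error")
  }
  if (anyNA(time_s) || anyNA(signal_fu)) {
    abort("Trace time and signal must not contain NA.",
          class = "capflowr_validation_error")
  }
  dt <- diff(time_s)
  bad <- which(dt <= 0)
  if (length(bad) > 0) {
    abort(
      sprintf("Trace time must be strictly increasing; first violation at index %d.",
              bad[1] + 1L),
      class = "capflowr_validation_error"
    )
  }
  if (any(time_s < 0)) {
    abort("Trace time must be non-negative.",
          class = "capflowr_validation_error")
  }
  invisible(TRUE)
}

#' Trace metadata accessors
#'
#' @param trace A [cap_trace()].
#' @return The channel label, pressure, or sample id stored on the trace.
#' @export
trace_channel <- function(trace) attr(trace, "channel") %||% NA_character_

#' @rdname trace_channel
#' @export
trace_pressure <- function(trace) attr(trace, "pressure_mbar") %||% NA_real_

#' @rdname trace_channel
#' @export
trace_sample_id <- function(trace) attr(trace, "sample_id") %||% NA_character_

#' Sampling interval of a trace
#'
#' Median sampling interval in seconds.  Errors when sampling is not
#' approximately uniform (max/min interval ratio of 1.5 or more), in which
#' case the trace must be resampled before window-based filtering.
#'
#' @param trace A [cap_trace()].
#' @param require_uniform Error on non-uniform sampling (default `TRUE`).
#' @return Sampling interval in seconds.
#' @export
trace_dt <- function(trace, require_uniform = TRUE) {
  dt <- diff(trace$time_s)
  if (require_uniform && max(dt) / min(dt) >= 1.5) {
    abort(
      "Trace sampling is not approximately uniform (max/min interval ratio >= 1.5); resample before filtering.",
      class = "capflowr_validation_error"
    )
  }
  median(dt)
}

#' Coerce a data frame to a trace
#'
#' @param x A data frame with a time column and a signal column.
#' @param time_col,signal_col Column names (defaults `time_s`, `signal_fu`).
#' @inheritParams cap_trace
#' @return A `cap_trace`.
#' @export
as_cap_trace <- function(x, time_col = "time_s", signal_col = "signal_fu",
                         channel = "alexa488", pressure_mbar = NA_real_,
                         sample_id = NA_character_, metadata = list()) {
  for (col in c(time_col, signal_col)) {
    if (!col %in% names(x)) {
      abort(sprintf("Column `%s` not found.", col),
            class = "capflowr_format_error")
    }
  }
  cap_trace(x[[time_col]], x[[signal_col]], channel = channel,
            pressure_mbar = pressure_mbar, sample_id = sample_id,
            metadata = metadata)
}

#' @export
print.cap_trace <- function(x, ...) {
  cat(sprintf("<cap_trace> channel=%s, n=%d, span=[%.4g, %.4g] s\n",
              trace_channel(x), nrow(x), min(x$time_s), max(x$time_s)))
  NextMethod()
}
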