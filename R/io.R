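#' Read a capillary trace from a CSV file
#'
#' Trace files are comma-separated with a header row, a `time_s` column and
#' one signal column per channel named `signal_<channel>_fu`
#' (e.g. `signal_alexa488_fu`, `signal_tht_fu`).  Multi-channel acquisitions
#' live as sibling columns in one file; each channel is read and analyzed as
#' an independent trace.
#'
#' @param path Path to the trace file.
#' @param channel Channel label selecting the signal column.
#' @return A [cap_trace()].
#' @export
read_trace <- function(path, channel = "alexa488") {
  if (!file.exists(path)) {
    abort(sprintf("Trace file not found: %s", path), class = "capflowr_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"time_s" %in% names(df)) {
    abort("Trace file must have a `time_s` column.",
          class = "capflowr_format_error")
  }
  sig_col <- paste0("signal_", channel, "_fu")
  if (!sig_col %in% names(df)) {
    abort(sprintf("Trace file has no column `%s` (channels present: %s).",
                  sig_col,
                  paste(trace_file_channels(names(df)), collapse = ", ")),
          class = "capflowr_format_error")
  }
  pressure <- attr(df, "pressure_mbar", exact = TRUE) %||% NA_real_
  cap_trace(df$time_s, df[[sig_col]], channel = channel,
            pressure_mbar = pressure, sample_id = basename(path))
}

trace_file_channels <- function(cols) {
  hits <- grep("^signal_(.+)_fu$", cols, value = TRUE)
  sub("^signal_(.+)_fu$", "\\1", hits)
}

#' Write one or more traces to a CSV file
#'
#' @param trace A [cap_trace()], or a list of traces sharing one time grid
#'   (written as sibling channel columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  traces <- if (inherits(trace, "cap_trace")) list(trace) else trace
  t0 <- traces[[1]]$time_s
  df <- tibble::tibble(time_s = t0)
  for (tr in traces) {
    stopifnot(inherits(tr, "cap_trace"))
    if (!isTRUE(all.equal(tr$time_s, t0))) {
      abort("All channels written to one file must share a time grid.",
            class = "capflowr_validation_error")
    }
    df[[paste0("signal_", trace_channel(tr), "_fu")]] <- tr$signal_fu
  }
  write_csv_checked(df, path)
  invisible(path)
}

write_csv_checked <- function(df, path) {
  ok <- tryCatch({
    readr::write_csv(df, path, progress = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(sprintf("Cannot write to %s: %s", path, conditionMessage(ok)),
          class = "capflowr_io_error")
  }
  invisible(path)
}

#' Write an analysis result to a structured text file
#'
#' Results (calibration curves, baseline results, peak tables, binding fits,
#' flow summaries, ...) are serialized as JSON with full numeric precision,
#' so a written file re-reads losslessly.  The object's class is recorded in
#' a `.type` field and restored by [read_results()].
#'
#' @param report A result object (classed list or data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(report, path) {
  payload <- serialize_result(report)
  ok <- tryCatch({
    writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                                null = "null", na = "null"), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(sprintf("Cannot write to %s: %s", path, conditionMessage(ok)),
          class = "capflowr_io_error")
  }
  invisible(path)
}

# scalar attributes carried across the file round trip for tabular results
.result_attrs <- c("threshold_used", "baseline_fu", "saturation_ceiling",
                   "channel", "n_saturated_excluded")

serialize_result <- function(report) {
  if (is.data.frame(report)) {
    attrs <- attributes(report)[intersect(.result_attrs, names(attributes(report)))]
    list(.type = class(report)[1],
         .kind = "data.frame",
         columns = as.list(as.data.frame(report)),
         attrs = attrs)
  } else if (is.list(report)) {
    fields <- lapply(unclass(report), function(x) {
      if (is.data.frame(x)) {
        list(.kind = "data.frame", columns = as.list(as.data.frame(x)))
      } else x
    })
    c(list(.type = class(report)[1], .kind = "list"), fields)
  } else {
    abort("Only list- or data-frame-like results can be serialized.",
          class = "capflowr_validation_error")
  }
}

#' Read a result file written by [write_results()]
#'
#' @param path Path to a result JSON file.
#' @return The result object with its class restored; numeric fields are
#'   recovered at full stored precision.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Result file not found: %s", path),
          class = "capflowr_io_error")
  }
  payload <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                                simplifyVector = TRUE)
  type <- payload$.type
  kind <- payload$.kind
  payload$.type <- NULL
  payload$.kind <- NULL
  if (identical(kind, "data.frame")) {
    out <- tibble::as_tibble(lapply(payload$columns, unlist_or_empty))
    for (a in names(payload$attrs)) attr(out, a) <- payload$attrs[[a]]
    class(out) <- unique(c(type, class(out)))
    return(out)
  }
  fields <- lapply(payload, function(x) {
    if (is.list(x) && identical(x$.kind, "data.frame")) {
      tibble::as_tibble(lapply(x$columns, unlist_or_empty))
    } else x
  })
  structure(fields, class = type)
}

unlist_or_empty <- function(x) {
  if (length(x) == 0) numeric(0) else x
}
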