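#' Construct a single-lead ECG trace
#'
#' An `ecg_trace` is a uniformly sampled single-lead voltage series with its
#' sampling rate and a recording start offset relative to the intervention
#' time (so event onset times can be expressed on the study clock).
#'
#' @param samples Numeric vector of voltages (mV). Must be non-empty and free
#'   of `NA`/`NaN`.
#' @param fs_hz Sampling rate in Hz (> 0).
#' @param t0 Start time of the first sample in seconds relative to the
#'   intervention (default 0).
#'
#' @return An object of class `ecg_trace`: a list with elements `samples`,
#'   `fs_hz` and `t0`.
#' @export
#' @examples
#' tr <- ecg_trace(sin(seq(0, 2 * pi, length.out = 1000)), fs_hz = 1000)
#' tr
ecg_trace <- function(samples, fs_hz, t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("`samples` must be non-empty")
  if (anyNA(samples)) stop("`samples` must not contain NA/NaN")
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || !is.finite(fs_hz) ||
      fs_hz <= 0) {
    stop("`fs_hz` must be a single positive number")
  }
  structure(
    list(samples = samples, fs_hz = as.numeric(fs_hz), t0 = as.numeric(t0)),
    class = "ecg_trace"
  )
}

#' @export
print.ecg_trace <- function(x, ...) {
  dur <- length(x$samples) / x$fs_hz
  cat(sprintf(
    "<ecg_trace> %d samples @ %g Hz (%.2f s), t0 = %g s\n",
    length(x$samples), x$fs_hz, dur, x$t0
  ))
  invisible(x)
}

#' @export
length.ecg_trace <- function(x) length(x$samples)

#' Time axis of a trace
#'
#' @param trace An [ecg_trace()].
#' @return Numeric vector of sample times in seconds (study clock).
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "ecg_trace"))
  trace$t0 + (seq_along(trace$samples) - 1) / trace$fs_hz
}

#' Remove baseline wander from a trace
#'
#' Applies a zero-phase high-pass Butterworth filter to suppress slow baseline
#' drift (respiration/movement artefact in telemetry recordings). Traces
#' generated without wander do not need this step.
#'
#' @param trace An [ecg_trace()].
#' @param highpass_hz High-pass corner frequency in Hz (default 0.5).
#' @return A cleaned [ecg_trace()].
#' @export
clean_trace <- function(trace, highpass_hz = 0.5) {
  stopifnot(inherits(trace, "ecg_trace"))
  if (highpass_hz <= 0 || highpass_hz >= trace$fs_hz / 2) {
    stop("`highpass_hz` must lie in (0, fs/2)")
  }
  bf <- signal::butter(2, highpass_hz / (trace$fs_hz / 2), type = "high")
  v <- as.numeric(signal::filtfilt(bf, trace$samples))
  ecg_trace(v, trace$fs_hz, trace$t0)
}

#' Write / read a trace as CSV with a YAML sidecar header
#'
#' The CSV holds two columns, `time_s` and `voltage_mV`; the sidecar
#' (`<path>.yaml`) records sampling rate, units, start offset and free-form
#' metadata (e.g. morphology stage, generator seed) so a trace file is
#' self-describing.
#'
#' @param trace An [ecg_trace()].
#' @param path CSV file path; the sidecar is written to `paste0(path, ".yaml")`.
#' @param meta Named list of extra metadata stored in the sidecar.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns an [ecg_trace()] with the sidecar metadata attached as attribute
#'   `"meta"`.
#' @export
write_trace_csv <- function(trace, path, meta = list()) {
  stopifnot(inherits(trace, "ecg_trace"))
  df <- data.frame(time_s = trace_times(trace), voltage_mV = trace$samples)
  utils::write.csv(df, path, row.names = FALSE)
  header <- c(
    list(fs_hz = trace$fs_hz, units = "mV", t0_s = trace$t0),
    meta
  )
  yaml::write_yaml(header, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) {
    header <- yaml::read_yaml(sidecar)
    fs <- header$fs_hz
    t0 <- if (!is.null(header$t0_s)) header$t0_s else df$time_s[1]
  } else {
    # infer fs from the time column when no sidecar is present
    fs <- 1 / stats::median(diff(df$time_s))
    t0 <- df$time_s[1]
    header <- list(fs_hz = fs, t0_s = t0)
  }
  tr <- ecg_trace(df$voltage_mV, fs, t0)
  attr(tr, "meta") <- header
  tr
}
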