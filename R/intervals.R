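# Interval metrics, including the murine rate-corrected QT.

#' Murine rate-corrected QT interval
#'
#' QTc = QT / sqrt(RR / 100) with both intervals in milliseconds. The
#' normalization to RR = 100 ms (600 bpm) is the murine analogue of the
#' human Bazett correction; at RR = 100 ms the correction is the identity.
#'
#' @param qt_ms QT interval(s) in ms (> 0).
#' @param rr_ms Preceding RR interval(s) in ms (> 0).
#' @return QTc in ms (vectorized).
#' @export
#' @examples
#' qtc_correct(50, 100)  # 50
#' qtc_correct(50, 400)  # 25
qtc_correct <- function(qt_ms, rr_ms) {
  if (any(!is.finite(qt_ms) | qt_ms <= 0)) stop("qt_ms must be > 0")
  if (any(!is.finite(rr_ms) | rr_ms <= 0)) stop("rr_ms must be > 0")
  qt_ms / sqrt(rr_ms / 100)
}

#' Summarize ECG intervals over a time window
#'
#' Means of RR, QRS, QT and QTc over the eligible beats of a recording
#' window (e.g. a baseline epoch 48 h post infarction). QTc is computed per
#' beat and then averaged; beats without a measurable T end are excluded
#' from the QT/QTc means and counted in `n_qt_excluded`.
#'
#' @param beats Classified beat tibble with intervals and `time_s`.
#' @param window_s Numeric length-2: half-open window `[start, end)` in
#'   seconds on the beat time axis.
#' @param timepoint_id Label for the summary row.
#' @param sinus_only Use sinus-labeled beats only (default `TRUE`); ectopic
#'   beats distort QRS/QT means.
#' @param qtc_rr `"beat"` (default): each beat's own preceding RR enters its
#'   QTc; `"window_mean"`: the window-mean RR is used for every beat.
#' @return One-row tibble: `timepoint_id`, `n_beats`, `n_qt_excluded`,
#'   `mean_rr_ms`, `mean_qrs_ms`, `mean_qt_ms`, `mean_qtc_ms`.
#' @export
summarize_timepoint <- function(beats, window_s, timepoint_id = "timepoint",
                                sinus_only = TRUE,
                                qtc_rr = c("beat", "window_mean")) {
  qtc_rr <- match.arg(qtc_rr)
  stopifnot(is.data.frame(beats), length(window_s) == 2L,
            window_s[2] > window_s[1])
  sel <- beats$time_s >= window_s[1] & beats$time_s < window_s[2]
  if (sinus_only) sel <- sel & beats$label == "sinus"
  b <- beats[sel, , drop = FALSE]
  if (nrow(b) == 0L) {
    stop("empty window: no eligible beats in [", window_s[1], ", ",
         window_s[2], ")")
  }
  mean_rr <- mean(b$rr_ms, na.rm = TRUE)
  ok_qt <- !is.na(b$qt_ms) & !is.na(b$rr_ms)
  qtc <- if (any(ok_qt)) {
    rr_use <- if (qtc_rr == "beat") b$rr_ms[ok_qt] else mean_rr
    mean(qtc_correct(b$qt_ms[ok_qt], rr_use))
  } else {
    NA_real_
  }
  tibble::tibble(
    timepoint_id = timepoint_id,
    n_beats = nrow(b),
    n_qt_excluded = sum(is.na(b$qt_ms)),
    mean_rr_ms = mean_rr,
    mean_qrs_ms = mean(b$qrs_ms, na.rm = TRUE),
    mean_qt_ms = mean(b$qt_ms, na.rm = TRUE),
    mean_qtc_ms = qtc
  )
}
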