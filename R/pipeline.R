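#' Full trace-to-events analysis
#'
#' Chains R-peak detection, fiducial delineation, interval computation, VPB
#' classification and rhythm-pattern detection.
#'
#' @param trace An [ecg_trace()].
#' @param delineation A [delineation_config()].
#' @param classifier A [classifier_config()].
#' @param ... Passed to [detect_r_peaks()].
#' @return List with `beats` (classified beat tibble) and `events` (tibble
#'   from [classify_patterns()]).
#' @export
#' @examples
#' eg <- simulate_ecg(n_beats = 150, spec = arrhythmia_spec(vpb_rate = 30),
#'                    seed = 4)
#' res <- analyze_trace(eg$trace)
#' res$events
analyze_trace <- function(trace, delineation = delineation_config(),
                          classifier = classifier_config(), ...) {
  peaks <- detect_r_peaks(trace, ...)
  if (length(peaks) == 0L) {
    return(list(
      beats = tibble::tibble(),
      events = tibble::tibble(
        etype = character(), start_beat = integer(), end_beat = integer(),
        n_vpb = integer(), onset_time_s = numeric()
      )
    ))
  }
  beats <- delineate_beats(trace, peaks, delineation)
  beats <- classify_beats(beats, classifier)
  events <- classify_patterns(beats$label, beats$time_s)
  list(beats = beats, events = events)
}
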