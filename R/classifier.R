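# Rule-based ventricular premature beat (VPB) classification.
#
# A beat is ectopic when it deviates morphologically from the preceding
# normal complexes (R amplitude or QRS width), occurs prematurely relative
# to them, and either lacks a P wave or shows a shortened PR interval.

#' VPB classifier configuration
#'
#' Thresholds operationalize a qualitative definition: morphology deviation
#' and prematurity are judged against running medians over the preceding
#' non-VPB beats. `reference_window = 1` reproduces the literal
#' single-preceding-beat comparison.
#'
#' @param morph_dev_frac Minimum relative deviation in R amplitude OR QRS
#'   duration vs the reference (default 0.20).
#' @param prematurity_frac A beat is premature when its RR is below this
#'   fraction of the reference RR (default 0.80).
#' @param pr_short_frac PR counts as shortened below this fraction of the
#'   reference PR (default 0.75).
#' @param early_cycle_frac Beats with RR below this fraction of the
#'   reference RR fall in the early cardiac cycle (default 0.70, must be
#'   <= `prematurity_frac`). An ectopic this early cannot carry a conducted
#'   P wave - any apparent deflection in its P window is the preceding
#'   beat's T wave - so the P/PR criterion is considered satisfied without
#'   consulting the (unreliable) P measurement; only later-cycle premature
#'   beats must show an absent P or a shortened PR.
#' @param reference_window Number of preceding non-VPB beats in the running
#'   medians (>= 3 unless 1, default 10).
#' @param rule `"and"` (default): morphology deviation AND prematurity AND
#'   the P/PR clause. `"or"`: morphology OR prematurity (each still gated by
#'   the P/PR clause), for the looser reading of the definition.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(morph_dev_frac = 0.20, prematurity_frac = 0.80,
                              pr_short_frac = 0.75, early_cycle_frac = 0.70,
                              reference_window = 10,
                              rule = c("and", "or")) {
  rule <- match.arg(rule)
  for (f in c(morph_dev_frac, prematurity_frac, pr_short_frac,
              early_cycle_frac)) {
    if (!is.numeric(f) || f <= 0 || f >= 1) {
      stop("all fractions must lie in (0, 1)")
    }
  }
  if (early_cycle_frac > prematurity_frac) {
    stop("early_cycle_frac must be <= prematurity_frac")
  }
  reference_window <- as.integer(reference_window)
  if (reference_window != 1L && reference_window < 3L) {
    stop("reference_window must be 1 (literal rule) or >= 3")
  }
  structure(
    list(morph_dev_frac = morph_dev_frac,
         prematurity_frac = prematurity_frac,
         pr_short_frac = pr_short_frac,
         early_cycle_frac = early_cycle_frac,
         reference_window = reference_window,
         rule = rule),
    class = "classifier_config"
  )
}

# running-median reference over the last `window` sinus-labeled beats
# strictly before `upto_index`
.reference <- function(beats, labels, upto_index, window) {
  prior <- which(labels[seq_len(upto_index - 1L)] == "sinus")
  if (length(prior) < 3L) {
    stop("insufficient history: need >= 3 preceding sinus beats")
  }
  use <- utils::tail(prior, window)
  med <- function(x) {
    x <- x[!is.na(x)]
    if (length(x)) stats::median(x) else NA_real_
  }
  list(
    ref_r_amplitude = med(beats$r_amplitude_mv[use]),
    ref_qrs = med(beats$qrs_ms[use]),
    ref_rr = med(beats$rr_ms[use]),
    ref_pr = med(beats$pr_ms[use])
  )
}

#' Reference profile of the preceding normal beats
#'
#' Medians of R amplitude, QRS duration, RR and PR over the last
#' `config$reference_window` sinus-labeled beats strictly before
#' `upto_index`.
#'
#' @param beats Beat tibble with intervals and a `label` column.
#' @param upto_index Beat index the reference is computed for.
#' @param config A [classifier_config()].
#' @return Named list: `ref_r_amplitude`, `ref_qrs`, `ref_rr`, `ref_pr`.
#' @export
reference_profile <- function(beats, upto_index, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  .reference(beats, beats$label, upto_index, config$reference_window)
}

#' Classify beats as sinus or VPB
#'
#' Labels are assigned left to right, so each decision depends only on
#' preceding beats. The first `reference_window` beats are provisionally
#' labeled sinus to seed the reference medians and flagged in the
#' `bootstrap` column.
#'
#' @param beats Beat tibble from [delineate_beats()] (intervals computed).
#' @param config A [classifier_config()].
#' @return The beat tibble with `label` set to `"sinus"`/`"vpb"` and a
#'   logical `bootstrap` column.
#' @export
#' @examples
#' eg <- simulate_ecg(n_beats = 120, spec = arrhythmia_spec(vpb_rate = 20),
#'                    noise_sd = 0, seed = 2)
#' peaks <- detect_r_peaks(eg$trace)
#' beats <- delineate_beats(eg$trace, peaks)
#' table(classify_beats(beats)$label)
classify_beats <- function(beats, config = classifier_config()) {
  stopifnot(is.data.frame(beats), inherits(config, "classifier_config"))
  nb <- nrow(beats)
  w <- config$reference_window
  if (nb <= max(w, 3L)) {
    stop("too few beats to seed references: need more than ",
         max(w, 3L), " beats")
  }
  labels <- rep("sinus", nb)
  seed_n <- max(w, 3L)

  for (i in seq.int(seed_n + 1L, nb)) {
    ref <- .reference(beats, labels, i, w)
    amp_dev <- abs(beats$r_amplitude_mv[i] - ref$ref_r_amplitude) /
      abs(ref$ref_r_amplitude)
    qrs_dev <- abs(beats$qrs_ms[i] - ref$ref_qrs) / ref$ref_qrs
    morph <- (!is.na(amp_dev) && amp_dev >= config$morph_dev_frac) ||
      (!is.na(qrs_dev) && qrs_dev >= config$morph_dev_frac)
    premature <- !is.na(beats$rr_ms[i]) && !is.na(ref$ref_rr) &&
      beats$rr_ms[i] < config$prematurity_frac * ref$ref_rr
    early_cycle <- !is.na(beats$rr_ms[i]) && !is.na(ref$ref_rr) &&
      beats$rr_ms[i] < config$early_cycle_frac * ref$ref_rr
    p_clause <- early_cycle || is.na(beats$p_onset[i]) ||
      (!is.na(beats$pr_ms[i]) && !is.na(ref$ref_pr) &&
         beats$pr_ms[i] < config$pr_short_frac * ref$ref_pr)
    is_vpb <- if (config$rule == "and") {
      morph && premature && p_clause
    } else {
      (morph || premature) && p_clause
    }
    if (is_vpb) labels[i] <- "vpb"
  }
  beats$label <- labels
  beats$bootstrap <- seq_len(nb) <= seed_n
  beats
}
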