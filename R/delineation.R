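# R-peak detection and per-beat fiducial delineation for murine ECG.
#
# Detection is Pan-Tompkins-style: bandpass, differentiate, square,
# moving-window integrate, threshold, refractory. Delineation locates the
# classical landmarks (P onset, Q onset, R peak, S end, T end) by
# noise-adaptive threshold searches in physiologic windows scaled to mouse
# heart rates. Sample indices are 1-based; intervals are half-open.

#' Delineation configuration
#'
#' Search windows are scaled to murine defaults (QRS ~12 ms, QT ~50 ms,
#' RR ~100 ms at 600 bpm).
#'
#' @param q_window_ms Search window for the Q onset before the R peak (ms).
#' @param s_window_ms Search window for the S end after the R peak (ms).
#' @param t_frac T-end search extends this fraction of the current RR past R.
#' @param p_window_ms P search window before the Q onset (ms); additionally
#'   bounded below by the previous beat's T end.
#' @param thr_floor_mv Minimum boundary threshold (mV); the working threshold
#'   is `max(3 * noise SD, thr_floor_mv)`.
#' @param p_presence_floor_mv,t_presence_floor_mv Minimum peak deflection
#'   (mV) for a P / T wave to count as present.
#' @return An object of class `delineation_config`.
#' @export
delineation_config <- function(q_window_ms = 15, s_window_ms = 15,
                               t_frac = 0.6, p_window_ms = 40,
                               thr_floor_mv = 0.008,
                               p_presence_floor_mv = 0.02,
                               t_presence_floor_mv = 0.02) {
  stopifnot(q_window_ms > 0, s_window_ms > 0, t_frac > 0, t_frac < 1,
            p_window_ms > 0, thr_floor_mv > 0)
  structure(
    list(q_window_ms = q_window_ms, s_window_ms = s_window_ms,
         t_frac = t_frac, p_window_ms = p_window_ms,
         thr_floor_mv = thr_floor_mv,
         p_presence_floor_mv = p_presence_floor_mv,
         t_presence_floor_mv = t_presence_floor_mv),
    class = "delineation_config"
  )
}

# robust noise SD: MAD of the residual after a short running-median smooth
.noise_sd <- function(v) {
  k <- 9L
  if (length(v) <= k) return(stats::mad(v))
  stats::mad(v - stats::runmed(v, k))
}

#' Detect R peaks in an ECG trace
#'
#' Bandpass filter, squared derivative, moving-window integration, fixed
#' fraction-of-maximum threshold on the integrated energy, refractory-period
#' enforcement, then refinement of each peak to the local maximum of the raw
#' signal. The short default refractory (30 ms) accommodates murine heart
#' rates up to 900 bpm.
#'
#' @param trace An [ecg_trace()] at least 2 s long.
#' @param refractory_ms Minimum distance between detected peaks (ms).
#' @param band_hz Bandpass corner frequencies in Hz.
#' @param threshold_frac Fraction of the maximum integrated energy used as
#'   detection threshold.
#' @return Strictly increasing integer vector of R-peak sample indices.
#'   A flat (zero-variance) trace yields an empty result with a warning.
#' @export
detect_r_peaks <- function(trace, refractory_ms = 30, band_hz = c(5, 60),
                           threshold_frac = 0.15) {
  stopifnot(inherits(trace, "ecg_trace"))
  v <- trace$samples
  fs <- trace$fs_hz
  if (length(v) < 2 * fs) stop("trace too short: need >= 2 s of signal")
  if (max(abs(v - stats::median(v))) < 1e-9) {
    warning("flat signal: no R peaks detected")
    return(integer(0))
  }

  nyq <- fs / 2
  band <- pmin(band_hz, nyq * 0.99) / nyq
  bf <- signal::butter(2, band, type = "pass")
  bp <- as.numeric(signal::filtfilt(bf, v))
  e <- c(0, diff(bp))^2
  k <- max(3L, as.integer(round(0.010 * fs)))
  ei <- as.numeric(stats::filter(e, rep(1 / k, k), sides = 2))
  ei[is.na(ei)] <- 0

  thr <- threshold_frac * max(ei)
  n <- length(ei)
  cand <- which(ei >= thr &
                  ei >= c(-Inf, ei[-n]) &
                  ei >= c(ei[-1], -Inf))
  if (length(cand) == 0L) return(integer(0))

  refr <- as.integer(round(refractory_ms * fs / 1000))
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) == 0L || i - keep[length(keep)] > refr) {
      keep <- c(keep, i)
    } else if (ei[i] > ei[keep[length(keep)]]) {
      keep[length(keep)] <- i  # larger energy within refractory wins
    }
  }

  # refine to the raw-signal maximum near each energy peak
  half <- as.integer(round(0.010 * fs))
  peaks <- vapply(keep, function(i) {
    lo <- max(1L, i - half)
    hi <- min(length(v), i + half)
    lo + which.max(v[lo:hi]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # re-enforce refractory after refinement
  if (length(peaks) > 1L) {
    out <- peaks[1L]
    for (p in peaks[-1L]) {
      if (p - out[length(out)] > refr) {
        out <- c(out, p)
      } else if (v[p] > v[out[length(out)]]) {
        out[length(out)] <- p
      }
    }
    peaks <- out
  }
  as.integer(peaks)
}

# first index in idx whose deviation exceeds thr, NA if none
.first_above <- function(dev, idx, thr) {
  hit <- idx[dev[idx] >= thr]
  if (length(hit)) hit[1L] else NA_integer_
}

.last_above <- function(dev, idx, thr) {
  hit <- idx[dev[idx] >= thr]
  if (length(hit)) hit[length(hit)] else NA_integer_
}

#' Delineate per-beat fiducials around detected R peaks
#'
#' For each R peak, locates the Q onset (earliest departure from the
#' isoelectric line within `q_window_ms` before R), the S end (latest
#' departure within `s_window_ms` after R), the T end (return of the smoothed
#' signal to baseline after the T peak, searched up to `t_frac` of the
#' current RR) and the P onset (threshold crossing in the window before the
#' Q onset, bounded below by the previous beat's T end). A P wave is marked
#' absent when no deflection in its window reaches 3x the local noise SD;
#' a T end that does not return to baseline inside its window is set to `NA`
#' and the beat is excluded from QT statistics.
#'
#' @param trace An [ecg_trace()].
#' @param r_peaks Integer vector of R-peak sample indices (>= 1 peak).
#' @param config A [delineation_config()].
#' @return Tibble with one row per beat: `beat`, `p_onset`, `q_onset`,
#'   `r_peak`, `s_end`, `t_end` (sample indices, `NA` when absent),
#'   `r_amplitude_mv`, `time_s`, `label` (all `"unclassified"`), plus the
#'   interval columns filled by [compute_intervals()].
#' @export
delineate_beats <- function(trace, r_peaks, config = delineation_config()) {
  stopifnot(inherits(trace, "ecg_trace"),
            inherits(config, "delineation_config"))
  r_peaks <- as.integer(r_peaks)
  if (length(r_peaks) < 1L) stop("need >= 1 R peak")
  v <- trace$samples
  fs <- trace$fs_hz
  n <- length(v)
  ms <- function(x) as.integer(round(x * fs / 1000))

  base <- stats::median(v)
  dev <- abs(v - base)
  sd_raw <- .noise_sd(v)
  thr <- max(3 * sd_raw, config$thr_floor_mv)

  # 7-sample moving average for the low-amplitude P and T searches
  vs <- as.numeric(stats::filter(v, rep(1 / 7, 7), sides = 2))
  vs[is.na(vs)] <- v[is.na(vs)]
  dev_s <- abs(vs - base)
  sd_s <- sd_raw / sqrt(7)
  thr_s <- max(3 * sd_s, config$thr_floor_mv)
  p_presence <- max(3 * sd_s, config$p_presence_floor_mv)
  t_presence <- max(3 * sd_s, config$t_presence_floor_mv)

  nb <- length(r_peaks)
  p_onset <- q_onset <- s_end <- t_end <- rep(NA_integer_, nb)
  prev_t_end <- NA_integer_

  for (i in seq_len(nb)) {
    r <- r_peaks[i]
    # Q onset
    q_lo <- max(1L, r - ms(config$q_window_ms))
    qi <- if (q_lo <= r - 1L) .first_above(dev, q_lo:(r - 1L), thr) else NA
    if (is.na(qi)) qi <- max(1L, r - ms(2))
    q_onset[i] <- qi
    # S end
    s_hi <- min(n, r + ms(config$s_window_ms))
    si <- if (r + 1L <= s_hi) .last_above(dev, (r + 1L):s_hi, thr) else NA
    if (is.na(si)) si <- min(n, r + ms(2))
    s_end[i] <- si
    # T end: search from just past S to t_frac of the current (preceding)
    # RR, but never into the next beat's QRS search region
    rr_smp <- if (i > 1L) {
      r - r_peaks[i - 1L]
    } else if (nb > 1L) {
      r_peaks[2L] - r
    } else {
      ms(100)
    }
    t_lo <- si + ms(2)
    t_hi <- min(n, r + as.integer(round(config$t_frac * rr_smp)))
    if (i < nb) t_hi <- min(t_hi, r_peaks[i + 1L] - ms(config$q_window_ms))
    if (t_hi - t_lo >= 2L) {
      win <- t_lo:t_hi
      pk <- win[which.max(dev_s[win])]
      if (dev_s[pk] >= t_presence) {
        # return to baseline must persist for 3 samples (noise dips right
        # after the T peak must not truncate the wave)
        after <- pk:t_hi
        below <- dev_s[after] < thr_s
        persist <- below &
          c(below[-1L], TRUE) &
          c(below[-(1:2)], TRUE, TRUE)
        hit <- which(persist)
        # must return to baseline inside the window, else T end is unknown
        t_end[i] <- if (length(hit)) after[hit[1L]] - 1L else NA_integer_
      }
    }
    # P onset: window before the QRS, not reaching into the previous T.
    # The upper bound is anchored to R (not the measured Q onset, which sits
    # on the R upstroke when the Q wave is below the noise floor) so the
    # smoothed QRS edge cannot masquerade as a P peak.
    p_lo <- max(1L, qi - ms(config$p_window_ms))
    if (!is.na(prev_t_end)) p_lo <- max(p_lo, prev_t_end + 2L)
    p_hi <- min(qi, r - ms(9)) - ms(2)
    if (p_hi - p_lo >= 2L) {
      win <- p_lo:p_hi
      pk <- win[which.max(dev_s[win])]
      if (dev_s[pk] >= p_presence) {
        # walk back from the P peak to a persistent (3-sample) return to
        # baseline; isolated noise dips on the upstroke are ignored
        seg <- dev_s[p_lo:pk] < thr_s
        p_onset[i] <- if (length(seg) < 3L) {
          p_lo
        } else {
          persist <- seg &
            c(TRUE, seg[-length(seg)]) &
            c(TRUE, TRUE, seg[-(length(seg) - 0:1)])
          hit <- which(persist)
          if (length(hit)) p_lo + hit[length(hit)] else p_lo
        }
      }
    }
    # when the T end is unknown, bound the next P search conservatively
    prev_t_end <- if (!is.na(t_end[i])) t_end[i] else si + ms(40)
  }

  beats <- tibble::tibble(
    beat = seq_len(nb),
    p_onset = p_onset,
    q_onset = q_onset,
    r_peak = r_peaks,
    s_end = s_end,
    t_end = t_end,
    r_amplitude_mv = v[r_peaks] - base,
    time_s = trace$t0 + (r_peaks - 1L) / fs,
    label = "unclassified"
  )
  compute_intervals(beats, fs)
}

#' Derive per-beat intervals from fiducials
#'
#' Fills `rr_ms` (from the previous beat's R peak; `NA` for the first beat),
#' `pr_ms` (`NA` when no P), `qrs_ms` and `qt_ms` (`NA` when the T end is
#' unknown), all in milliseconds.
#'
#' @param beats Beat tibble ordered by `r_peak`.
#' @param fs_hz Sampling rate the fiducial indices refer to.
#' @return The beat tibble with interval columns (re)computed.
#' @export
compute_intervals <- function(beats, fs_hz) {
  stopifnot(is.data.frame(beats), fs_hz > 0)
  if (is.unsorted(beats$r_peak)) stop("beats must be ordered by r_peak")
  to_ms <- 1000 / fs_hz
  beats$rr_ms <- c(NA_real_, diff(beats$r_peak)) * to_ms
  beats$pr_ms <- (beats$q_onset - beats$p_onset) * to_ms
  beats$qrs_ms <- (beats$s_end - beats$q_onset) * to_ms
  beats$qt_ms <- (beats$t_end - beats$q_onset) * to_ms
  beats
}
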