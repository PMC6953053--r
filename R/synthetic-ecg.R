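# Synthetic murine telemetry ECG with known ground truth.
#
# Beats are rendered as sums of compact-support raised-cosine (Hann) lobes,
# one per wave (P, Q, R, S, T) plus a flat-topped ST displacement lobe.
# Compact support means every template landmark (wave onset/end) is an exact
# sample position, so delineation accuracy can be scored against truth.

# -- sinus beat template (ms relative to the R peak) --------------------------
# QRS 12 ms (Q onset -6, S end +6), QT 50 ms (T end +44), PR 35 ms
# (P onset -41), P duration 10 ms. Defaults match murine telemetry at
# 600 bpm / RR 100 ms.
.template <- list(
  qrs_half_ms = 6,
  qt_ms       = 50,
  pr_ms       = 35,
  p_dur_ms    = 10,
  p_amp_mv    = 0.10,
  r_amp_mv    = 1.00,
  t_amp_mv    = 0.25
)

#' Morphology stage presets for infarction-phase ECG
#'
#' Each stage parameterizes how the beat template is deformed by the
#' corresponding phase of a two-stage infarction experiment: ST-segment
#' displacement (elevation during acute occlusion, depression with deep S
#' waves seven days after ischemia-reperfusion), T-wave amplitude scaling
#' (hyperacute T during occlusion) and Q/S-wave deepening (Q-wave development
#' after reperfusion and late after reinfarction).
#'
#' @param stage_id One of `"baseline"`, `"occlusion"`, `"reperfusion"`,
#'   `"day7_prereinfarct"`, `"reinfarct_acute"`, `"reinfarct_12h"`.
#' @param st_offset,t_amplitude_scale,q_depth,s_depth Optional overrides of
#'   the preset values: ST-segment offset (mV), T amplitude multiplier,
#'   Q-wave amplitude (mV, <= 0), S-wave amplitude (mV, <= 0).
#'
#' @return An object of class `morphology_stage`.
#' @export
#' @examples
#' morphology_stage("occlusion")
morphology_stage <- function(stage_id = c("baseline", "occlusion",
                                          "reperfusion", "day7_prereinfarct",
                                          "reinfarct_acute", "reinfarct_12h"),
                             st_offset = NULL, t_amplitude_scale = NULL,
                             q_depth = NULL, s_depth = NULL) {
  stage_id <- match.arg(stage_id)
  presets <- list(
    baseline          = list(st_offset =  0.00, t_amplitude_scale = 1.0,
                             q_depth = -0.05, s_depth = -0.15),
    occlusion         = list(st_offset =  0.25, t_amplitude_scale = 2.0,
                             q_depth = -0.05, s_depth = -0.15),
    reperfusion       = list(st_offset =  0.00, t_amplitude_scale = 1.0,
                             q_depth = -0.20, s_depth = -0.15),
    day7_prereinfarct = list(st_offset = -0.15, t_amplitude_scale = 1.0,
                             q_depth = -0.20, s_depth = -0.40),
    reinfarct_acute   = list(st_offset =  0.25, t_amplitude_scale = 1.2,
                             q_depth = -0.25, s_depth = -0.20),
    reinfarct_12h     = list(st_offset =  0.15, t_amplitude_scale = 1.0,
                             q_depth = -0.30, s_depth = -0.20)
  )
  p <- presets[[stage_id]]
  if (!is.null(st_offset)) p$st_offset <- st_offset
  if (!is.null(t_amplitude_scale)) p$t_amplitude_scale <- t_amplitude_scale
  if (!is.null(q_depth)) p$q_depth <- q_depth
  if (!is.null(s_depth)) p$s_depth <- s_depth

  if (p$q_depth > 0 || p$s_depth > 0) stop("q_depth and s_depth must be <= 0")
  baseline_q <- presets$baseline$q_depth
  if (stage_id %in% c("occlusion", "reinfarct_acute") && p$st_offset <= 0) {
    stop(stage_id, " requires st_offset > 0 (acute injury current)")
  }
  if (stage_id == "day7_prereinfarct" && p$st_offset >= 0) {
    stop("day7_prereinfarct requires st_offset < 0 (ST depression)")
  }
  if (stage_id %in% c("reperfusion", "reinfarct_12h") &&
      p$q_depth >= baseline_q) {
    stop(stage_id, " requires q_depth below the baseline value (Q development)")
  }
  structure(c(list(stage_id = stage_id), p), class = "morphology_stage")
}

#' @export
print.morphology_stage <- function(x, ...) {
  cat(sprintf(
    "<morphology_stage> %s: ST %+0.2f mV, T x%g, Q %0.2f mV, S %0.2f mV\n",
    x$stage_id, x$st_offset, x$t_amplitude_scale, x$q_depth, x$s_depth
  ))
  invisible(x)
}

#' Specify the arrhythmia burden of a synthetic recording
#'
#' @param vpb_rate Expected number of isolated VPBs per minute at the nominal
#'   600 bpm heart rate, i.e. per 600 beats (Poisson-drawn).
#' @param n_bigeminy,n_trigeminy Number of bigeminy / trigeminy episodes to
#'   inject. Each episode is the minimal repeating pattern with three VPBs
#'   (V,N,V,N,V resp. V,N,N,V,N,N,V).
#' @param vt_run_lengths Integer vector of VT run lengths, each >= 4; one VT
#'   event is injected per element.
#' @param salvo_run_lengths Integer vector of salvo run lengths, each 2 or 3.
#' @param prematurity_factor Coupling interval of an ectopic beat as a
#'   fraction of the sinus RR (0 < f < 1, default 0.6). The post-ectopic
#'   pause is compensatory: (2 - f) x sinus RR.
#' @param vpb_qrs_scale QRS width multiplier for ectopic beats (> 1,
#'   default 2).
#' @param vpb_r_scale R amplitude multiplier for ectopic beats (default 1.4).
#'
#' @return An object of class `arrhythmia_spec`.
#' @export
arrhythmia_spec <- function(vpb_rate = 0, n_bigeminy = 0, n_trigeminy = 0,
                            vt_run_lengths = integer(),
                            salvo_run_lengths = integer(),
                            prematurity_factor = 0.6, vpb_qrs_scale = 2,
                            vpb_r_scale = 1.4) {
  vt_run_lengths <- as.integer(vt_run_lengths)
  salvo_run_lengths <- as.integer(salvo_run_lengths)
  if (vpb_rate < 0 || n_bigeminy < 0 || n_trigeminy < 0) {
    stop("rates and event counts must be >= 0")
  }
  if (length(vt_run_lengths) && any(vt_run_lengths < 4L)) {
    stop("every VT run length must be >= 4")
  }
  if (length(salvo_run_lengths) && !all(salvo_run_lengths %in% c(2L, 3L))) {
    stop("every salvo run length must be 2 or 3")
  }
  if (prematurity_factor <= 0 || prematurity_factor >= 1) {
    stop("prematurity_factor must lie in (0, 1)")
  }
  if (vpb_qrs_scale <= 1) stop("vpb_qrs_scale must be > 1")
  structure(
    list(
      vpb_rate = vpb_rate,
      n_bigeminy = as.integer(n_bigeminy),
      n_trigeminy = as.integer(n_trigeminy),
      n_salvo = length(salvo_run_lengths),
      n_vt = length(vt_run_lengths),
      vt_run_lengths = vt_run_lengths,
      salvo_run_lengths = salvo_run_lengths,
      prematurity_factor = prematurity_factor,
      vpb_qrs_scale = vpb_qrs_scale,
      vpb_r_scale = vpb_r_scale
    ),
    class = "arrhythmia_spec"
  )
}

# label pattern and event type for each injected episode
.event_patterns <- function(spec) {
  pats <- list()
  add <- function(etype, labels) {
    pats[[length(pats) + 1L]] <<- list(etype = etype, labels = labels)
  }
  for (len in spec$vt_run_lengths) add("vt", rep("vpb", len))
  for (len in spec$salvo_run_lengths) add("salvo", rep("vpb", len))
  if (spec$n_bigeminy > 0) {
    for (i in seq_len(spec$n_bigeminy)) {
      add("bigeminy", c("vpb", "sinus", "vpb", "sinus", "vpb"))
    }
  }
  if (spec$n_trigeminy > 0) {
    for (i in seq_len(spec$n_trigeminy)) {
      add("trigeminy",
          c("vpb", "sinus", "sinus", "vpb", "sinus", "sinus", "vpb"))
    }
  }
  pats
}

#' Generate a ground-truth beat-label sequence with injected arrhythmias
#'
#' Places the requested arrhythmia episodes (VT runs, salvos, bigeminy and
#' trigeminy patterns, Poisson-drawn isolated VPBs) at random non-overlapping
#' positions in a sinus background. Episodes are separated by at least
#' `min_gap` sinus beats so that no two injected episodes can spell a longer
#' pattern together, and the first `min_lead` beats are sinus so downstream
#' classifiers can bootstrap their reference profile.
#'
#' @param n_beats Total number of beats (positive integer). Must be large
#'   enough to hold all requested episodes; otherwise a capacity error is
#'   raised.
#' @param spec An [arrhythmia_spec()].
#' @param seed Integer seed; the output is deterministic for a fixed seed.
#' @param min_gap Minimum number of sinus beats between episodes (default 3;
#'   values below 3 allow adjacent isolated VPBs to imitate bigeminy or
#'   trigeminy spacing and make ground truth ambiguous).
#' @param min_lead Minimum number of leading sinus beats (default 10).
#'
#' @return An object of class `simulation_truth`: list with `labels`
#'   (character vector, `"sinus"`/`"vpb"`), `events` (tibble: `etype`,
#'   `start_beat`, `end_beat`, `n_vpb`), and the generating `spec`.
#' @export
#' @examples
#' truth <- generate_label_sequence(
#'   50, arrhythmia_spec(vt_run_lengths = 5), seed = 7
#' )
#' truth$events
generate_label_sequence <- function(n_beats, spec, seed,
                                    min_gap = 3L, min_lead = 10L) {
  stopifnot(inherits(spec, "arrhythmia_spec"))
  n_beats <- as.integer(n_beats)
  if (n_beats < 1L) stop("`n_beats` must be a positive integer")
  min_gap <- max(0L, as.integer(min_gap))
  min_lead <- max(0L, as.integer(min_lead))

  withr::with_seed(as.integer(seed), {
    pats <- .event_patterns(spec)
    n_iso <- stats::rpois(1L, spec$vpb_rate * n_beats / 600)
    if (n_iso > 0) {
      for (i in seq_len(n_iso)) {
        pats[[length(pats) + 1L]] <- list(etype = "vpb_isolated",
                                          labels = "vpb")
      }
    }
    n_ev <- length(pats)
    labels <- rep("sinus", n_beats)
    if (n_ev == 0L) {
      events <- tibble::tibble(
        etype = character(), start_beat = integer(),
        end_beat = integer(), n_vpb = integer()
      )
    } else {
      pats <- pats[sample.int(n_ev)]
      spans <- vapply(pats, function(p) length(p$labels), integer(1))
      fixed <- sum(spans) + min_lead + min_gap * (n_ev - 1L)
      free <- n_beats - fixed
      if (free < 0L) {
        stop(sprintf(
          "capacity error: %d beats cannot hold the requested events (need >= %d)",
          n_beats, fixed
        ))
      }
      # distribute the free sinus beats over the n_ev + 1 gaps
      extra <- if (free > 0L) {
        tabulate(sample.int(n_ev + 1L, free, replace = TRUE), n_ev + 1L)
      } else {
        integer(n_ev + 1L)
      }
      gap_before <- c(min_lead, rep(min_gap, n_ev - 1L)) +
        extra[seq_len(n_ev)]
      start <- integer(n_ev)
      pos <- 0L
      for (i in seq_len(n_ev)) {
        pos <- pos + gap_before[i]
        start[i] <- pos + 1L
        labels[seq.int(start[i], length.out = spans[i])] <- pats[[i]]$labels
        pos <- pos + spans[i]
      }
      events <- tibble::tibble(
        etype = vapply(pats, `[[`, character(1), "etype"),
        start_beat = start,
        end_beat = start + spans - 1L,
        n_vpb = vapply(pats, function(p) sum(p$labels == "vpb"), integer(1))
      )
      events <- events[order(events$start_beat), , drop = FALSE]
    }
    structure(
      list(labels = labels, events = events, spec = spec,
           n_beats = n_beats),
      class = "simulation_truth"
    )
  })
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf(
    "<simulation_truth> %d beats, %d vpb, %d injected events\n",
    x$n_beats, sum(x$labels == "vpb"), nrow(x$events)
  ))
  invisible(x)
}

# Hann lobe: amp * 0.5 * (1 - cos(2*pi*(t-a)/(b-a))) on [a, b], 0 outside.
# a, b in (possibly fractional) sample units; adds in place into `v`.
.add_lobe <- function(v, a, b, amp) {
  if (b <= a || amp == 0) return(v)
  i0 <- max(1L, ceiling(a))
  i1 <- min(length(v), floor(b))
  if (i1 < i0) return(v)
  idx <- i0:i1
  v[idx] <- v[idx] + amp * 0.5 * (1 - cos(2 * pi * (idx - a) / (b - a)))
  v
}

#' Render a voltage trace from a ground-truth label sequence
#'
#' Each beat is the sum of raised-cosine lobes for P, Q, R, S and T plus a
#' flat ST-displacement lobe whose amplitude/polarity comes from the
#' morphology stage. Ectopic (VPB) beats are rendered without a P wave, with
#' QRS landmarks widened by `spec$vpb_qrs_scale` and R amplitude scaled by
#' `spec$vpb_r_scale`, at the premature coupling interval; the post-ectopic
#' pause is compensatory. Gaussian noise and optional sinusoidal baseline
#' wander are added on top.
#'
#' @param truth A [generate_label_sequence()] result.
#' @param stage A [morphology_stage()] (or stage id string).
#' @param hr_bpm Sinus heart rate in beats per minute (300-900; default 600).
#' @param fs_hz Sampling rate in Hz (>= 500; default 1000).
#' @param noise_sd Gaussian noise SD in mV (default 0.05).
#' @param seed Integer seed for the noise draw.
#' @param wander_amp_mv,wander_hz Optional baseline wander amplitude (mV,
#'   default 0 = off) and frequency (Hz).
#' @param t0 Recording start offset in seconds on the study clock.
#'
#' @return A list of class `synthetic_ecg` with elements `trace`
#'   ([ecg_trace()]), `fiducials` (tibble of true per-beat landmark sample
#'   indices: `beat`, `label`, `p_onset`, `q_onset`, `r_peak`, `s_end`,
#'   `t_end`, `time_s`) and `truth` (the input truth with `onset_time_s`
#'   added to its events).
#' @export
synthesize_trace <- function(truth, stage = "baseline", hr_bpm = 600,
                             fs_hz = 1000, noise_sd = 0.05, seed = 1,
                             wander_amp_mv = 0, wander_hz = 1, t0 = 0) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (is.character(stage)) stage <- morphology_stage(stage)
  stopifnot(inherits(stage, "morphology_stage"))
  if (hr_bpm < 300 || hr_bpm > 900) {
    stop("`hr_bpm` outside the murine-plausible range 300-900")
  }
  if (fs_hz < 500) stop("`fs_hz` must be >= 500")

  spec <- truth$spec
  tpl <- .template
  labels <- truth$labels
  n <- length(labels)
  base_rr <- 60000 / hr_bpm
  f <- spec$prematurity_factor

  # RR preceding each beat (ms); first beat anchored at 60 ms
  rr <- rep(base_rr, n)
  if (n > 1L) {
    for (i in 2:n) {
      rr[i] <- if (labels[i] == "vpb") {
        f * base_rr
      } else if (labels[i - 1L] == "vpb") {
        (2 - f) * base_rr
      } else {
        base_rr
      }
    }
  }
  r_ms <- 60 + cumsum(c(0, rr[-1L]))
  ms2smp <- fs_hz / 1000

  w <- ifelse(labels == "vpb", spec$vpb_qrs_scale, 1)
  q_on_ms <- r_ms - tpl$qrs_half_ms * w
  s_end_ms <- r_ms + tpl$qrs_half_ms * w
  t_end_ms <- q_on_ms + tpl$qt_ms
  p_on_ms <- ifelse(labels == "vpb", NA_real_, q_on_ms - tpl$pr_ms)

  n_samples <- ceiling((max(t_end_ms) + 80) * ms2smp)
  v <- numeric(n_samples)

  for (i in seq_len(n)) {
    is_vpb <- labels[i] == "vpb"
    amp_scale <- if (is_vpb) spec$vpb_r_scale else 1
    r <- r_ms[i] * ms2smp + 1
    qh <- tpl$qrs_half_ms * w[i] * ms2smp
    # P (sinus only)
    if (!is_vpb) {
      a <- p_on_ms[i] * ms2smp + 1
      v <- .add_lobe(v, a, a + tpl$p_dur_ms * ms2smp, tpl$p_amp_mv)
    }
    # QRS: Q, R, S lobes (widths scale with w)
    v <- .add_lobe(v, r - qh, r - qh / 3, stage$q_depth * amp_scale)
    v <- .add_lobe(v, r - 2 * qh / 3, r + 2 * qh / 3,
                   tpl$r_amp_mv * amp_scale)
    v <- .add_lobe(v, r + qh / 3, r + qh, stage$s_depth * amp_scale)
    # ST displacement from S end to T end
    se <- s_end_ms[i] * ms2smp + 1
    te <- t_end_ms[i] * ms2smp + 1
    v <- .add_lobe(v, se, te, stage$st_offset)
    # T wave
    t_start <- se + max(2, min(10, 0.3 * (t_end_ms[i] - s_end_ms[i]))) *
      ms2smp
    v <- .add_lobe(v, t_start, te, tpl$t_amp_mv * stage$t_amplitude_scale)
  }

  withr::with_seed(as.integer(seed), {
    if (noise_sd > 0) v <- v + stats::rnorm(n_samples, 0, noise_sd)
    if (wander_amp_mv > 0) {
      ph <- stats::runif(1, 0, 2 * pi)
      tt <- (seq_len(n_samples) - 1) / fs_hz
      v <- v + wander_amp_mv * sin(2 * pi * wander_hz * tt + ph)
    }
  })

  smp <- function(ms) as.integer(round(ms * ms2smp)) + 1L
  fiducials <- tibble::tibble(
    beat = seq_len(n),
    label = labels,
    p_onset = ifelse(is.na(p_on_ms), NA_integer_, smp(p_on_ms)),
    q_onset = smp(q_on_ms),
    r_peak = smp(r_ms),
    s_end = smp(s_end_ms),
    t_end = smp(t_end_ms),
    time_s = t0 + (smp(r_ms) - 1L) / fs_hz
  )
  events <- truth$events
  if (nrow(events)) {
    events$onset_time_s <- fiducials$time_s[events$start_beat]
  } else {
    events$onset_time_s <- numeric(0)
  }
  truth$events <- events

  structure(
    list(trace = ecg_trace(v, fs_hz, t0), fiducials = fiducials,
         truth = truth),
    class = "synthetic_ecg"
  )
}

#' One-call synthetic telemetry recording
#'
#' Convenience wrapper chaining [generate_label_sequence()] and
#' [synthesize_trace()] with a single seed.
#'
#' @inheritParams generate_label_sequence
#' @inheritParams synthesize_trace
#' @return See [synthesize_trace()].
#' @export
simulate_ecg <- function(n_beats = 600, spec = arrhythmia_spec(),
                         stage = "baseline", hr_bpm = 600, fs_hz = 1000,
                         noise_sd = 0.05, seed = 1, ...) {
  truth <- generate_label_sequence(n_beats, spec, seed = seed)
  synthesize_trace(truth, stage = stage, hr_bpm = hr_bpm, fs_hz = fs_hz,
                   noise_sd = noise_sd, seed = seed + 1L, ...)
}

#' Fit a negative-binomial dispersion from a mean and SD
#'
#' Solves `var = mu + mu^2 / size` for `size`. When the reported SD implies
#' at most Poisson variance the dispersion is effectively infinite; a large
#' finite cap is returned so the draw degenerates to (near-)Poisson.
#'
#' @param mean,sd Published per-group mean and standard deviation.
#' @return Negative-binomial `size` parameter.
#' @export
fit_nb_dispersion <- function(mean, sd) {
  stopifnot(mean >= 0, sd >= 0)
  if (mean == 0) return(Inf)
  excess <- sd^2 - mean
  if (excess <= 0) return(1e8)
  mean^2 / excess
}

#' Simulate a per-animal arrhythmia count table
#'
#' Draws per-animal event counts from a negative binomial around supplied
#' per-group/per-window/per-type means, mimicking the overdispersed counts of
#' telemetry studies (reported SDs typically exceed the means).
#'
#' @param group_means Data frame with columns `group`, `window`, `etype`,
#'   `mean` (optionally `intervention`, and `dispersion` to override the
#'   global dispersion cell by cell, e.g. fit from published SDs with
#'   [fit_nb_dispersion()]); one row per table cell.
#' @param n_animals Named integer vector: animals per group (each >= 2).
#' @param dispersion Negative-binomial `size` (> 0; may be `Inf` for
#'   Poisson). Ignored for rows carrying their own `dispersion`.
#' @param seed Integer seed; identical seeds give identical tables.
#'
#' @return Tibble with one row per animal x cell: `animal_id`, `group`,
#'   (`intervention`,) `window`, `etype`, `count`.
#' @export
simulate_count_table <- function(group_means, n_animals, dispersion, seed) {
  group_means <- as.data.frame(group_means)
  need <- c("group", "window", "etype", "mean")
  if (!all(need %in% names(group_means))) {
    stop("`group_means` needs columns group, window, etype, mean")
  }
  if (any(group_means$mean < 0)) stop("means must be >= 0")
  if (!is.numeric(dispersion) || length(dispersion) != 1L ||
      is.na(dispersion) || dispersion <= 0) {
    stop("`dispersion` must be a single positive number")
  }
  if (is.null(names(n_animals)) ||
      !all(unique(group_means$group) %in% names(n_animals))) {
    stop("`n_animals` must be named by group")
  }
  if (any(n_animals < 2)) stop("need >= 2 animals per group")

  cap <- function(d) if (is.infinite(d)) 1e8 else d
  row_disp <- if ("dispersion" %in% names(group_means)) {
    if (any(!is.na(group_means$dispersion) & group_means$dispersion <= 0)) {
      stop("`dispersion` must be a single positive number")
    }
    ifelse(is.na(group_means$dispersion), dispersion,
           group_means$dispersion)
  } else {
    rep(dispersion, nrow(group_means))
  }
  withr::with_seed(as.integer(seed), {
    out <- lapply(seq_len(nrow(group_means)), function(i) {
      row <- group_means[i, , drop = FALSE]
      n <- n_animals[[row$group]]
      cnt <- stats::rnbinom(n, size = cap(row_disp[i]), mu = row$mean)
      cbind(
        data.frame(animal_id = paste0(row$group, "_", seq_len(n))),
        row[rep(1L, n),
            setdiff(names(row), c("mean", "dispersion")), drop = FALSE],
        data.frame(count = cnt)
      )
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    tibble::as_tibble(res)
  })
}
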