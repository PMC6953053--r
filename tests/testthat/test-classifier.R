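# crafted beat tables at fs = 1000 (indices in samples = ms)
make_beats <- function(n, rr = 100) {
  r <- cumsum(rep(rr, n)) + 60L
  beats <- tibble::tibble(
    beat = seq_len(n),
    p_onset = r - 41L,
    q_onset = r - 6L,
    r_peak = as.integer(r),
    s_end = r + 6L,
    t_end = r + 44L,
    r_amplitude_mv = 1,
    time_s = r / 1000,
    label = "unclassified"
  )
  compute_intervals(beats, 1000)
}

# turn beat i into an ectopic complex: premature by `coupling` ms, no P,
# QRS widened by `qrs_scale`, R amplitude scaled
make_vpb <- function(beats, i, coupling = 60, qrs_scale = 2, amp_scale = 1.4) {
  shift <- beats$rr_ms[i] - coupling
  beats$r_peak[i] <- beats$r_peak[i] - shift
  beats$q_onset[i] <- beats$r_peak[i] - 6L * qrs_scale
  beats$s_end[i] <- beats$r_peak[i] + 6L * qrs_scale
  beats$t_end[i] <- beats$q_onset[i] + 50L
  beats$p_onset[i] <- NA_integer_
  beats$r_amplitude_mv[i] <- amp_scale
  beats$time_s[i] <- beats$r_peak[i] / 1000
  compute_intervals(beats, 1000)
}

test_that("perfectly regular identical beats are all sinus", {
  out <- classify_beats(make_beats(30))
  expect_true(all(out$label == "sinus"))
  expect_identical(sum(out$bootstrap), 10L)
})

test_that("a wide, premature, P-less complex is a VPB", {
  beats <- make_vpb(make_beats(30), 20)
  out <- classify_beats(beats)
  expect_identical(out$label[20], "vpb")
  expect_identical(sum(out$label == "vpb"), 1L)
})

test_that("prematurity without morphology deviation is not a VPB", {
  beats <- make_beats(30)
  # early beat, normal morphology, normal PR, P present
  shift <- 40L
  beats$r_peak[20] <- beats$r_peak[20] - shift
  for (col in c("p_onset", "q_onset", "s_end", "t_end")) {
    beats[[col]][20] <- beats[[col]][20] - shift
  }
  beats <- compute_intervals(beats, 1000)
  out <- classify_beats(beats)
  expect_identical(out$label[20], "sinus")
})

test_that("morphology deviation without prematurity is not a VPB (AND rule)", {
  beats <- make_beats(30)
  beats$r_amplitude_mv[20] <- 2  # on-time but tall
  out <- classify_beats(beats)
  expect_identical(out$label[20], "sinus")
  # the looser OR reading flags it only if the P/PR clause also fires
  beats$p_onset[20] <- NA_integer_
  beats <- compute_intervals(beats, 1000)
  out_or <- classify_beats(beats, classifier_config(rule = "or"))
  expect_identical(out_or$label[20], "vpb")
})

test_that("an absent P or a shortened PR both satisfy the P clause", {
  # later-cycle coupling (75% of RR): the P/PR criterion is consulted.
  # shortened PR variant: premature and wide, with a short-PR P wave
  beats <- make_vpb(make_beats(30), 20, coupling = 75)
  beats$p_onset[20] <- beats$q_onset[20] - 20L  # PR 20 ms vs reference 35
  beats <- compute_intervals(beats, 1000)
  out <- classify_beats(beats)
  expect_identical(out$label[20], "vpb")
  # normal PR blocks the clause for a later-cycle beat
  beats$p_onset[20] <- beats$q_onset[20] - 35L
  beats <- compute_intervals(beats, 1000)
  out <- classify_beats(beats)
  expect_identical(out$label[20], "sinus")
})

test_that("an early-cycle ectopic is a VPB regardless of the P measurement", {
  # at 60% coupling the previous T overlaps the P window, so an apparent
  # normal-PR P wave must not rescue the beat into sinus
  beats <- make_vpb(make_beats(30), 20, coupling = 60)
  beats$p_onset[20] <- beats$q_onset[20] - 35L
  beats <- compute_intervals(beats, 1000)
  out <- classify_beats(beats)
  expect_identical(out$label[20], "vpb")
  expect_error(classifier_config(early_cycle_frac = 0.9),
               "early_cycle_frac")
})

test_that("reference profile matches brute-force medians on random history", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      n <- sample(15:40, 1)
      beats <- make_beats(n)
      beats$r_amplitude_mv <- runif(n, 0.8, 1.2)
      beats$qrs_ms <- runif(n, 10, 14)
      beats$rr_ms <- c(NA, runif(n - 1, 90, 110))
      beats$pr_ms <- runif(n, 30, 40)
      beats$label <- "sinus"
      i <- sample(12:n, 1)
      w <- sample(c(1L, 3L, 10L), 1)
      cfg <- classifier_config(reference_window = w)
      ref <- reference_profile(beats, i, cfg)
      idx <- utils::tail(seq_len(i - 1L), w)
      expect_equal(ref$ref_r_amplitude, median(beats$r_amplitude_mv[idx]))
      expect_equal(ref$ref_qrs, median(beats$qrs_ms[idx]))
      expect_equal(ref$ref_rr, median(beats$rr_ms[idx], na.rm = TRUE))
      expect_equal(ref$ref_pr, median(beats$pr_ms[idx]))
    }
  })
})

test_that("a single outlier does not move a window-10 reference median", {
  beats <- make_beats(20)
  beats$r_amplitude_mv[15] <- 5
  beats$label <- "sinus"
  ref <- reference_profile(beats, 20, classifier_config())
  expect_equal(ref$ref_r_amplitude, 1)
})

test_that("labels are causal: truncation never changes earlier labels", {
  eg <- simulate_ecg(n_beats = 200, spec = busy_spec(), noise_sd = 0.05,
                     seed = 21)
  beats <- delineate_beats(eg$trace, detect_r_peaks(eg$trace))
  full <- classify_beats(beats)
  for (k in c(50, 120, 180)) {
    part <- classify_beats(beats[1:k, ])
    expect_identical(part$label, full$label[1:k])
  }
})

test_that("classification needs enough beats and a valid config", {
  expect_error(classify_beats(make_beats(8)), "too few beats")
  expect_error(classifier_config(morph_dev_frac = 1.5), "fractions")
  expect_error(classifier_config(reference_window = 2), "reference_window")
  expect_error(reference_profile(make_beats(30), 3), "insufficient history")
})
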