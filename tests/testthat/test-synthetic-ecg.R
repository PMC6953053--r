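test_that("an all-zero spec yields pure sinus and no events", {
  truth <- generate_label_sequence(100, arrhythmia_spec(), seed = 1)
  expect_identical(truth$labels, rep("sinus", 100))
  expect_identical(nrow(truth$events), 0L)
})

test_that("a single requested VT run is injected exactly", {
  truth <- generate_label_sequence(
    50, arrhythmia_spec(vt_run_lengths = 5), seed = 7
  )
  expect_identical(nrow(truth$events), 1L)
  ev <- truth$events
  expect_identical(ev$etype, "vt")
  expect_identical(ev$n_vpb, 5L)
  span <- ev$start_beat:ev$end_beat
  expect_true(all(truth$labels[span] == "vpb"))
  expect_identical(sum(truth$labels == "vpb"), 5L)
})

test_that("label generation is deterministic and errors on over-capacity", {
  spec <- arrhythmia_spec(vpb_rate = 40, vt_run_lengths = c(4, 6),
                          salvo_run_lengths = c(2, 3), n_bigeminy = 1)
  t1 <- generate_label_sequence(400, spec, seed = 3)
  t2 <- generate_label_sequence(400, spec, seed = 3)
  expect_identical(t1$labels, t2$labels)
  expect_identical(t1$events, t2$events)
  expect_error(
    generate_label_sequence(12, arrhythmia_spec(vt_run_lengths = c(5, 5)),
                            seed = 1),
    "capacity"
  )
})

test_that("spec validation rejects malformed arrhythmia requests", {
  expect_error(arrhythmia_spec(vt_run_lengths = 3), ">= 4")
  expect_error(arrhythmia_spec(salvo_run_lengths = 4), "2 or 3")
  expect_error(arrhythmia_spec(prematurity_factor = 1.2), "prematurity")
  expect_error(arrhythmia_spec(vpb_qrs_scale = 0.9), "vpb_qrs_scale")
  expect_error(arrhythmia_spec(vpb_rate = -1), ">= 0")
})

test_that("injected events carry labels consistent with their type", {
  for (seed in 1:20) {
    truth <- generate_label_sequence(500, busy_spec(), seed = seed)
    for (k in seq_len(nrow(truth$events))) {
      ev <- truth$events[k, ]
      span <- truth$labels[ev$start_beat:ev$end_beat]
      expect_identical(sum(span == "vpb"), as.integer(ev$n_vpb))
      if (ev$etype == "vt") {
        expect_true(all(span == "vpb") && length(span) >= 4)
      }
      if (ev$etype == "salvo") {
        expect_true(all(span == "vpb") && length(span) %in% 2:3)
      }
    }
  }
})

test_that("pattern detector recovers injected events exactly (seed sweep)", {
  for (seed in 1:100) {
    truth <- generate_label_sequence(400, busy_spec(), seed = seed)
    det <- classify_patterns(truth$labels)
    expect_identical(det$etype, truth$events$etype)
    expect_identical(det$start_beat, truth$events$start_beat)
    expect_identical(det$end_beat, truth$events$end_beat)
  }
})

test_that("morphology stage presets respect the infarction-phase invariants", {
  expect_gt(morphology_stage("occlusion")$st_offset, 0)
  expect_gt(morphology_stage("reinfarct_acute")$st_offset, 0)
  expect_lt(morphology_stage("day7_prereinfarct")$st_offset, 0)
  q_base <- morphology_stage("baseline")$q_depth
  expect_lt(morphology_stage("reperfusion")$q_depth, q_base)
  expect_lt(morphology_stage("reinfarct_12h")$q_depth, q_base)
  expect_error(morphology_stage("occlusion", st_offset = -0.1), "st_offset")
})

test_that("ST-segment voltage rises under occlusion relative to baseline", {
  truth <- generate_label_sequence(60, arrhythmia_spec(), seed = 2)
  st_mean <- function(stage) {
    eg <- synthesize_trace(truth, stage = stage, noise_sd = 0, seed = 1)
    f <- eg$fiducials
    v <- eg$trace$samples
    mean(vapply(seq_len(nrow(f)), function(i) {
      mean(v[(f$s_end[i] + 2):(f$s_end[i] + 8)])
    }, numeric(1)))
  }
  expect_gt(st_mean("occlusion"), st_mean("baseline"))
  expect_lt(st_mean("day7_prereinfarct"), st_mean("baseline"))
})

test_that("ectopic template QRS width is vpb_qrs_scale x the sinus width", {
  spec <- arrhythmia_spec(vt_run_lengths = 4, vpb_qrs_scale = 2)
  truth <- generate_label_sequence(40, spec, seed = 9)
  eg <- synthesize_trace(truth, noise_sd = 0, seed = 1)
  f <- eg$fiducials
  qrs <- f$s_end - f$q_onset
  expect_equal(
    unique(qrs[f$label == "vpb"]),
    2 * unique(qrs[f$label == "sinus"])
  )
  expect_true(all(is.na(f$p_onset[f$label == "vpb"])))
  expect_true(all(!is.na(f$p_onset[f$label == "sinus"])))
})

test_that("synthesis is deterministic and validates its inputs", {
  truth <- generate_label_sequence(30, arrhythmia_spec(), seed = 1)
  a <- synthesize_trace(truth, noise_sd = 0.05, seed = 11)
  b <- synthesize_trace(truth, noise_sd = 0.05, seed = 11)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_error(synthesize_trace(truth, hr_bpm = 200), "300-900")
  expect_error(synthesize_trace(truth, fs_hz = 250), "fs_hz")
})

test_that("count simulation hits requested means and is reproducible", {
  gm <- data.frame(
    group = c("URI", "MIC"), window = "0-12h", etype = "vpb",
    mean = c(5, 0)
  )
  n <- c(URI = 10000L, MIC = 5L)
  tab <- simulate_count_table(gm, n, dispersion = 1, seed = 42)
  uri <- tab$count[tab$group == "URI"]
  expect_lt(abs(mean(uri) - 5) / 5, 0.02)
  expect_true(all(tab$count[tab$group == "MIC"] == 0))
  tab2 <- simulate_count_table(gm, n, dispersion = 1, seed = 42)
  expect_identical(tab, tab2)
  expect_error(simulate_count_table(gm, n, dispersion = 0, seed = 1),
               "dispersion")
  expect_error(simulate_count_table(gm, c(URI = 1L, MIC = 5L), 1, 1),
               ">= 2 animals")
})

test_that("negative-binomial dispersion fitting inverts the variance formula", {
  size <- fit_nb_dispersion(1105, 1146.72)
  expect_equal(1105 + 1105^2 / size, 1146.72^2)
  expect_identical(fit_nb_dispersion(0, 0), Inf)
  expect_gt(fit_nb_dispersion(5, 1), 1e7)  # under-dispersed -> near-Poisson
})
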