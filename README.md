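# murineECG

Quantification of ventricular arrhythmias in murine telemetry ECG.

Mouse models of myocardial infarction — a coronary (LAD) ligation, often
followed a week later by a second intervention — are read out largely
through continuous telemetry ECG: how many ventricular premature beats
(VPB), bigeminy/trigeminy episodes (BG/TG), salvos and ventricular
tachycardia (VT) runs each animal develops, in which time window after the
intervention, and whether a treatment changes those counts. `murineECG`
implements that entire analysis chain for researchers running such studies:

* **R-peak detection** tuned to murine rates (300–900 bpm): bandpass +
  squared-derivative energy with a 30 ms refractory period;
* **beat delineation** of the classical landmarks (start of P, start of Q,
  R, end of S, end of T) with noise-adaptive thresholds;
* **VPB classification** by the field's rule: morphology deviation from the
  preceding non-VPB complexes (R amplitude or QRS width, ≥ 20 %) *and*
  prematurity (RR < 80 % of reference) *and* an absent P wave (early cardiac
  cycle) or shortened PR (later cycle);
* **rhythm patterns** with disjoint tallies and precedence
  VT > salvo > trigeminy > bigeminy > isolated VPB, where VT is a run of
  ≥ 4 consecutive VPBs, a salvo 2–3, bigeminy ≥ 3 VPBs in V,N alternation
  and trigeminy ≥ 3 VPBs in a V,N,N cycle;
* **interval metrics** including the murine rate-corrected QT,

  QTc = QT / √(RR / 100)   (QT, RR in ms),

  which is the identity at the murine resting RR of 100 ms (600 bpm);
* **study statistics**: event stratification into half-open windows
  0–15 min, 15–45 min and 45 min–12 h post intervention (0–12 h derived as
  their sum), per-animal count tables with group mean ± SD, and two-sided
  Mann–Whitney U comparisons (exact by enumeration for small tie-free
  samples) at p ≤ 0.05;
* a fully parameterized **synthetic telemetry generator** with known ground
  truth — post-infarction morphology stages (ST elevation, hyperacute T,
  Q-wave development, deep S with ST depression) and injected arrhythmia
  events — so every stage of the pipeline is testable without animal data.

## Worked example

Simulate one minute of noisy telemetry carrying 40 isolated VPBs/min, one
five-beat VT run, two salvos and a bigeminy on acute-reinfarction
morphology, then run the full pipeline:

```r
library(murineECG)

spec <- arrhythmia_spec(vpb_rate = 40, vt_run_lengths = 5,
                        salvo_run_lengths = c(2, 3), n_bigeminy = 1)
eg  <- simulate_ecg(n_beats = 600, spec = spec, stage = "reinfarct_acute",
                    noise_sd = 0.05, seed = 1)
res <- analyze_trace(eg$trace)

count_by_type(res$events)
#>   etype count
#> 1 vpb      36
#> 2 bg_tg     1
#> 3 salvo     2
#> 4 vt        1

summarize_timepoint(res$beats, c(0, 60))
#>   timepoint_id n_beats n_qt_excluded mean_rr_ms mean_qrs_ms mean_qt_ms mean_qtc_ms
#> 1    timepoint     551             0        103       14.52      47.02       46.47
```

The event table reproduces the injected burden exactly (36 isolated VPBs
were drawn for this seed, plus the requested patterns). The timepoint
summary averages the 551 sinus beats: RR ≈ 103 ms (600 bpm plus
compensatory pauses), QRS ≈ 15 ms and QTc ≈ 46 ms on this noise level and
morphology. Group comparison of per-animal counts:

```r
mann_whitney(c(12, 30, 41, 7, 120), c(0, 1, 0, 3, 2, 1))
#> Mann-Whitney U = 30 (n = 5 vs 6), p = 0.004358 [normal_approx] *
```

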