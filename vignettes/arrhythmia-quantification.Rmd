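---
title: "Quantifying ventricular arrhythmias in murine telemetry ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ventricular arrhythmias in murine telemetry ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(murineECG)
```

## Scope and model

`murineECG` quantifies ventricular arrhythmias in single-lead telemetry ECG
from mice, the setting of post-infarction arrhythmia studies in which a
coronary (LAD) ligation is followed days later by a second intervention and
the arrhythmic burden of each animal is counted over defined
post-intervention windows. The pipeline is

1. **R-peak detection** — Pan–Tompkins-style: bandpass (5–60 Hz),
   squared derivative, 10-ms moving-window integration, fixed
   fraction-of-maximum energy threshold, 30-ms refractory period (murine
   rates reach 900 bpm, so the refractory must be far shorter than the
   human convention), and refinement of each detection to the local raw
   maximum.
2. **Delineation** — per beat, the classical landmarks: start of P, start
   of Q, R peak, end of S, end of T, located by noise-adaptive threshold
   searches in physiologic windows scaled to a 600-bpm mouse (Q within
   15 ms before R, S within 15 ms after, T up to 60 % of the preceding RR,
   P within 40 ms before the QRS but never before the previous beat's
   T end).
3. **VPB classification** — a beat is a ventricular premature beat when it
   (i) deviates ≥ 20 % from the running reference in R amplitude *or* QRS
   duration, (ii) is premature (RR < 80 % of reference), and (iii)
   satisfies the P criterion (below). References are medians over the last
   10 non-VPB beats; `reference_window = 1` reproduces the literal
   single-preceding-beat comparison.
4. **Pattern detection** — a greedy left-to-right scan over the beat-label
   sequence with precedence VT > salvo > trigeminy > bigeminy > isolated
   VPB: VT is ≥ 4 consecutive VPBs, a salvo 2–3, bigeminy ≥ 3 VPBs in
   strict V,N alternation, trigeminy ≥ 3 VPBs in a strict V,N,N cycle.
   Matches are maximal and every beat is consumed at most once, so the
   category tallies are disjoint.
5. **Interval metrics** — RR, PR, QRS, QT in milliseconds and the murine
   rate-corrected QT, $QT_c = QT / \sqrt{RR/100}$ (RR in ms); the
   normalization point RR = 100 ms is the 600-bpm murine resting rate, so
   the correction is the identity there.
6. **Study statistics** — events are assigned by onset time to half-open
   windows 0–15 min, 15–45 min and 45 min–12 h after the intervention
   (the 0–12 h union is always derived as their sum, never assigned
   independently), tabulated per animal, and compared between groups with
   a two-sided Mann–Whitney U test at p ≤ 0.05.

## The P criterion and the early cardiac cycle

The defining property of a VPB is ectopic ventricular origin: no conducted
P wave (early in the cycle) or a shortened PR (later in the cycle). We
implement this with two thresholds. Beats earlier than
`early_cycle_frac` (default 0.70) × reference RR are *early-cycle*: at such
coupling the previous beat's T wave overlaps the whole P search window, so
any apparent P deflection there is T-wave residue and the criterion is
taken as satisfied without consulting the measurement. Premature beats in
the band between `early_cycle_frac` and `prematurity_frac` must show an
absent P or PR < 75 % of reference. Collapsing these two cases into a bare
"absent P or short PR" test is tempting but wrong in practice: in noisy
recordings the T tail of a preceding ectopic is regularly delineated as a
"P" with a coincidentally normal PR, which would split VT runs into salvos.

Whether the source definition intends morphology *and* prematurity as a
conjunction or as alternatives cannot be settled from its wording; both
readings are available (`rule = "and"`, the default and the literal
reading, or `rule = "or"`).

## The synthetic generator

No public murine telemetry recordings accompany the study design this
package targets, so the generator is a first-class, tested module and every
accuracy claim below is made against its ground truth.

Beats are sums of compact-support raised-cosine (Hann) lobes, one per wave.
We chose compact support over the more common Gaussian bumps deliberately:
a Gaussian has no defined onset, whereas a Hann lobe starts and ends at
exact sample positions, so "delineation within 2 samples of truth" is a
meaningful, testable statement. The sinus template uses murine defaults:
RR 100 ms (600 bpm), QRS 12 ms (Q onset −6 ms to S end +6 ms around R),
QT 50 ms, PR 35 ms, P duration 10 ms, R amplitude 1 mV, P 0.1 mV,
T 0.25 mV. Ectopic beats have no P lobe, QRS landmarks widened by
`vpb_qrs_scale` (default 2), R amplitude × 1.4, a coupling interval of
`prematurity_factor` (default 0.6) × sinus RR and a compensatory
(2 − 0.6) × RR pause. Amplitudes are arbitrary-but-consistent millivolts;
the source material reports no calibration, and nothing downstream depends
on absolute scale.

Six morphology stages deform the template to mimic the infarction
narrative: acute occlusion (ST elevation +0.25 mV, hyperacute T × 2),
reperfusion (Q deepens to −0.20 mV), the day-7 pre-reinfarction state
(ST depression −0.15 mV, deep S −0.40 mV), acute reinfarction (ST
re-elevation) and 12 h post reinfarction (deep Q, residual ST elevation).

Injected events are placed at random non-overlapping positions with at
least 3 intervening sinus beats. A 2-beat gap — enough to keep runs from
merging — is *not* enough to keep ground truth unambiguous: three isolated
VPBs each 2 sinus beats apart spell V,N,N,V,N,N,V, which is exactly the
trigeminy pattern. The 3-beat minimum gap removes that ambiguity, which is
why the generator/detector agreement test can demand exact event-list
recovery over 100 seeds. The first 10 beats are always sinus so the
classifier can bootstrap its reference medians (those beats are flagged
`bootstrap`). `vpb_rate` is defined per 600 beats, i.e. per minute at the
nominal 600-bpm rate, because a label sequence has no time base of its own.

Per-animal count tables are simulated from a negative binomial. Published
per-group SDs in this field exceed the means severalfold, so a Poisson
model would understate between-animal variance badly;
`fit_nb_dispersion()` inverts $\mathrm{var} = \mu + \mu^2/k$ to recover a
dispersion from a published mean ± SD.

What the generator does **not** emulate: heart-rate variability and
rate drift (RR is deterministic given the labels), respiratory baseline
wander is off by default (a sinusoidal wander term and a matching
`clean_trace()` high-pass are available), electrode artefacts, fusion
beats, polymorphic VT, and P/T morphologies beyond single lobes. Passing
the recovery suites therefore demonstrates correctness of the algorithms
under controlled morphology and noise, not field performance on real
telemetry, where detection thresholds would need tuning per recording
system.

## Numerical choices and degenerate inputs

* Sample indices are 1-based (the R convention) with half-open interval
  semantics; intervals convert to ms via the sampling rate.
* The delineation noise floor is estimated as the MAD of the residual
  after a 9-point running median; boundary thresholds are
  max(3 × noise SD, 0.008 mV). P and T searches run on a 7-sample moving
  average with the SD scaled accordingly. Baseline is the global median of
  the trace.
* Returns to baseline (T end, P onset) must persist for 3 consecutive
  smoothed samples; isolated noise dips otherwise truncate T waves and
  manufacture false P onsets.
* A T wave that has not returned to baseline inside its search window
  (typical for beats inside fast runs, where the next QRS encroaches)
  gets `t_end = NA`; such beats are excluded from QT/QTc summaries and
  counted in `n_qt_excluded`.
* A flat trace yields zero R peaks with a warning, not an error; a trace
  shorter than 2 s is an error.
* Mann–Whitney: exact two-sided p by full enumeration of rank assignments
  when n ≤ 12 and tie-free. Otherwise a normal approximation with
  mid-ranks, tie-corrected variance and continuity correction — refined
  with an Edgeworth fourth-moment term computed from the exact
  finite-sampling moments of the rank sum (the rank distribution is
  symmetric, so there is no skewness term). The refinement matters: the
  plain continuity-corrected normal deviates from the exact p by up to
  0.0155 at n = 6 + 6, the Edgeworth-corrected version by < 0.005.
* Group summaries use the sample SD (n − 1); single-animal groups report
  SD 0 and are flagged. No multiple-testing adjustment is applied by
  default, matching the raw-p convention of the motivating study design;
  `compare_all(..., adjust = "holm")` is available.
* Time windows start at the intervention (ligation) time supplied by the
  user; onset times exactly on a boundary belong to the later window.

## Problem sizes used by the test suite

The bundled verification runs use 600-beat (≈ 60 s at 600 bpm) traces at
1 kHz and 0.05 mV Gaussian noise, 100 generator seeds for end-to-end
recovery, exhaustive enumeration of all 2^14 label sequences of length 14
against an independent regex/backtracking implementation of the pattern
grammar, and 500 negative-binomial replicates of the reinfarction VPB
group contrast (group sizes 9 vs 6, means and dispersions taken from the
bundled reference count summary). These sizes make the whole suite run in
a few minutes on one core while keeping the Monte-Carlo standard errors
well below the asserted margins.

## A worked example

```{r example, eval = FALSE}
spec <- arrhythmia_spec(vpb_rate = 40, vt_run_lengths = 5,
                        salvo_run_lengths = c(2, 3), n_bigeminy = 1)
eg <- simulate_ecg(n_beats = 600, spec = spec, stage = "reinfarct_acute",
                   noise_sd = 0.05, seed = 1)
res <- analyze_trace(eg$trace)
count_by_type(res$events)
summarize_timepoint(res$beats, c(0, 60))
```

## Known limitations

Single-lead only; no atrial arrhythmia or heart-block detection (a
third-degree block would appear as missed/slow beats, not as a classified
event); no quantitative ST scoring for infarct staging; no VT
morphology/duration subtyping; detection thresholds are tuned to the
synthetic morphology family and murine rates and should be revalidated
before use on other species or recording hardware.
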