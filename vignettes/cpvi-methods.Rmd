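---
title: "Detecting complex patient-ventilator interactions with sliding-window Sample Entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting complex patient-ventilator interactions with sliding-window Sample Entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Mechanically ventilated patients interact with the machine breath by
breath. Two kinds of disturbance matter clinically: sustained shifts in
respiratory rate, and clusters of asynchronous breaths — ineffective
expiratory efforts, double cycling, premature cycling, prolonged cycling
and reverse triggering. We call a 3-minute episode with a >50% rate
change and/or >30% asynchronous breaths a *complex patient-ventilator
interaction* (CP-VI). Detecting these episodes from the ventilator's own
airway flow and pressure waveforms, without breath segmentation and
without population-level cutoffs, is what this package does.

The premise is that CP-VI episodes make the waveforms *less regular*, and
that regularity can be tracked with Sample Entropy (SampEn) computed
directly on the raw signals. Each patient serves as their own control:
detection is triggered by a relative rise from the patient's personal
entropy baseline, not by an absolute entropy level, because baseline
entropy varies widely between patients, modes and circuit setups.

## The detector

For one channel (flow in L/min or airway pressure in cmH₂O):

1. **Decimation to 40 Hz.** SampEn cost is quadratic in window length, so
   the signal is reduced from its acquisition rate (200 Hz by default) to
   40 Hz — still far above the ≤ 5 Hz band where breathing lives. The
   anti-aliasing filter is a Hamming-windowed linear-phase FIR with
   cutoff at 16 Hz (0.8 × the 20 Hz output Nyquist), applied *centred*
   (zero phase) so that entropy windows keep raw-signal timestamps. The
   taps are normalized to exact unity DC gain, so constants pass through
   unchanged. Only integer decimation factors are supported; recordings
   at other rates are rejected rather than resampled.

2. **Sliding-window SampEn.** Windows of 30 s (N = 1200 samples) advance
   in 15-s strides (50% overlap), starting at the first sample; only
   complete windows are evaluated, so a 15-min segment holds 59 window
   positions. Within each window, with embedding dimension `m` and
   tolerance `r_abs = r_factor × SD(window)` (sample SD, n − 1), template
   vectors are compared under the Chebyshev distance with self-matches
   excluded; `B` counts matching pairs of length `m` over start indices
   `1..N−m`, `A` the pairs still matching at length `m + 1`, and
   `SampEn = −ln(A/B)` in nats.

3. **Smoothing.** The SE series is smoothed by an exponential moving
   average, `y_t = αx_t + (1−α)y_{t−1}` with `α = 2/(span+1)`, span 8
   windows (2 min of series time), initialized at the first defined
   value. The span parameterization (rather than a half-life) is a
   documented choice; the filter is exposed so a simple moving average
   can be compared.

4. **Features and baseline.** Each 15-min segment is summarized by the
   mean and the maximum of its defined smoothed SE points (a window
   belongs to the segment containing its centre). The personal baseline
   is the running minimum of the segment features seen so far,
   initialized by the first segment. A segment is flagged when the
   percent change `PC = 100 (feature − baseline)/baseline` strictly
   exceeds the threshold `Th`; ties are negative. The baseline is updated
   *after* a segment is evaluated, which makes detection causal: a quiet
   segment tightens the reference for later segments but never re-labels
   itself.

### Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `m` | 2 (flow), 4 (Paw) | samples | best-validated operating points from the repeated holdout search |
| `r_factor` | 0.2 | × window SD | classic SampEn range 0.1–0.25; 0.2 is a robust local maximum under the tolerance scan |
| `window_s` | 30 | s | long enough for ~5–15 breaths, short enough to localize a 3-min episode |
| `overlap_frac` | 0.5 | — | halves the feature variance without recomputing independent windows |
| `ema_span` | 8 | windows | 2 min of smoothing, matching the 3-min episode scale |
| `Th` | 25% (flow), 30% (Paw) | % of baseline | selected by the mean-MCC argmax |
| `min_defined` | 10 | SE points | a segment with fewer defined windows is unevaluable, not silently zero |

### Numerical conventions

- **Undefined SampEn.** If a window has zero SD (tolerance would be 0) or
  no template matches survive at `m` or `m + 1`, the value is `NA` — not
  a capped constant, which would inject artificial dynamics. Downstream
  aggregation simply skips `NA` points.
- **Index convention.** Template start indices run over `1..N−m` for both
  `B` and `A`, self-matches excluded, following the standard
  Richman–Moorman formulation.
- **The kernel.** For every ordered pair of start indices the run length
  of consecutive within-tolerance sample matches determines all template
  matches the pair participates in, so a single O(N²) diagonal sweep with
  a run-length histogram yields `A` and `B` for *every* `m` up to 20 at
  once, and all four tolerances share one sweep of the |xᵢ − xⱼ|
  differences. This is what makes the 640-combination grid search
  tractable; the test suite pins the kernel to a naive direct-definition
  counter at 1e-10.
- **MCC conventions.** A zero factor in the denominator gives MCC = 0;
  undefined ratios (e.g. PPV with no positive predictions) are `NA` and
  excluded from medians.
- **Tie-breaking.** At equal mean MCC the search prefers smaller `m`,
  then smaller `r`, then smaller `Th` (parsimony), then flow before Paw
  and max before mean for full determinism.
- **70/30 rounding.** `round(0.70 n)` segments go to the optimization
  side (92 segments split 64/28). Splits are segment-level by default;
  patient-grouped splitting is available via `stratify`-style wrappers if
  leakage control is wanted.
- **Degenerate detection inputs.** An unevaluable segment leaves the
  baseline untouched and yields `NA` PC; a zero baseline is an error
  (PC undefined) rather than an infinity.

### Known consequences of the baseline rule

The first evaluable segment defines the baseline and therefore can never
be flagged. If the recording *opens* inside a CP-VI, the baseline is
inflated and later episodes are under-called until a quieter spell
lowers it. `detect_cpvi(baseline_init_k = k)` optionally seeds the
baseline with the minimum over the first `k` evaluable segments to
soften this. Similarly, the EMA's ~2-min tail smears an episode's
elevated SE a short way into the following segment; at 15-min
granularity this occasionally elevates the segment after an episode that
ends exactly at a boundary.

## The optimization procedure

`build_se_cache()` computes SE features once for every
(channel, m, r) — entropy is never recomputed per repetition — and
`grid_search()` then scores detections per combination and threshold on
15 random 70/30 splits, all features and channels sharing identical
splits for comparability. `select_optimal()` takes the argmax of the
mean optimization-subset MCC and reports in how many repetitions the
winner was also that repetition's best. `validate_selected()` reports
medians and interquartile ranges of MCC, sensitivity, specificity,
accuracy, PPV and NPV on both subsets; optimization-side medians are
expected to sit slightly above validation-side ones, the usual
repeated-holdout optimism. `r_sensitivity()` re-runs the entropy at
0.01 steps around the selected tolerance on the same splits to check
that the optimum is not a knife-edge.

One master seed drives everything: it spawns per-repetition split seeds
and per-recording simulation seeds deterministically, so a full
`run_optimization()` is bit-identical across invocations.

## The synthetic benchmark generator

Clinical recordings cannot ship with the package, so
`simulate_recording()` builds labeled two-channel waveforms from
single-compartment breath templates:

- **PSV**: fast pressure rise to PEEP + support (defaults 8 + 10 cmH₂O)
  with decelerating inspiratory flow; **ACV** (volume-targeted): square
  inspiratory flow with a pressure ramp. Expiration is passive and
  scaled so each breath's flow integral is exactly zero.
- **Breath-to-breath variability**: timing jitter of 3% CV at baseline
  and 5% amplitude jitter. Jitter scales up with the severity of an
  active event — tachypnoea and asynchrony clusters disrupt rhythm in
  proportion to how hard the patient fights the ventilator.
- **Asynchrony morphologies**: parametric templates for the five types
  (e.g. an ineffective effort is a missed trigger — a lengthened cycle
  with a sharp mid-expiratory flow deflection toward zero and a small
  pressure dip). Every asynchronous breath additionally carries a
  low-frequency effort oscillation whose frequency, phase, timing and
  amplitude vary breath to breath, mimicking the erratic muscular
  activity of an actively interacting patient; prolonged and double
  cycling, the most effortful patterns, carry the strongest oscillation.
  Cluster density and effort amplitude co-vary by default (sicker
  patients fight more often *and* harder); `sim_event(effort_scale=)`
  decouples them.
- **Ground truth** is computed from the *realized* breath log, never the
  intended design: a 3-min tile is positive iff its mean realized rate
  deviates >50% from the baseline rate (the recording's configured rate;
  the reference window for this clinical definition is our documented
  choice) or >30% of its breaths are asynchronous; a 15-min segment is
  positive iff it overlaps a positive tile.

`make_benchmark_corpus()` assembles a labeled corpus (default 30
one-hour recordings, half PSV / half ACV, roughly half carrying events).
Event strengths are deliberately graded around the CP-VI definition —
strong episodes (rate ×1.8–2.2, clusters at 50–65%), mild positives just
above it, and benign sub-threshold episodes (rate ×1.2–1.24, 18%
clusters) in every negative recording — so that the detector's threshold
is genuinely exercised: the corpus is separable at `Th = 25%` on the
flow max feature, with the mildest events straddling that margin.
Events sit in segments 2+ (the first segment seeds the baseline) and
end ≥2 min before segment boundaries so the EMA tail stays within the
owning segment.

### What the generator does not emulate

Real recordings contain secretions, cardiogenic oscillations, circuit
leaks, suctioning artifacts, mode changes and drifting baselines; the
generator has none of these, and its noise is additive Gaussian (SD 2%
of channel amplitude) rather than physiological. Passing the synthetic
benchmark therefore demonstrates that the *pipeline* — entropy, baseline
tracking, thresholding, optimization — behaves as designed, not that the
shipped operating points transfer to any particular ICU population.
Tolerance re-optimization on local data is expected practice.

## Problem sizes

The shipped tests and the acceptance script use sizes chosen to exercise
every code path at desk scale: kernel-vs-oracle comparisons on 200
series up to N = 300; the analytic Gaussian check at N = 10,000 over 20
seeds; a 30-recording corpus (120 labeled segments) for the
640-combination, 15-repetition flow-channel grid search; 10-recording
corpora across five seeds for the fixed-operating-point check; and an
8-recording corpus for the bit-identity determinism check. A one-hour
recording's full (m, r) grid costs a few seconds on one core.

## Limitations

- Entropy reacts to *any* irregularity source; artifacts that real ICUs
  produce (suctioning, leaks) would raise SE and can false-positive a
  segment. The paper-level answer — expert validation of flagged
  segments — applies here too.
- The 15-min segment grid is fixed and episodes crossing segment
  boundaries dilute into both neighbours.
- Flow and Paw channels are evaluated separately by design; no fusion
  rule is provided.
- Proportional-assist and fully spontaneous modes are untested
  territory; the generator only emulates PSV and ACV.
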