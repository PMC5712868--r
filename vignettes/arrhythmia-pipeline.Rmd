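---
title: "An integrated arrhythmia pipeline for single-lead wearable ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrated arrhythmia pipeline for single-lead wearable ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgwatch)
```

`ecgwatch` detects the four arrhythmia targets that dominate ambulatory
single-lead screening — atrial premature complexes (APC, AAMI class S),
ventricular premature complexes (VPC, class V), atrial fibrillation (AF)
and ventricular fibrillation (VF) — with a chain of deliberately
low-complexity algorithms of the kind that run in real time on wearable
hardware. This vignette describes each stage's model and assumptions, the
tunable parameters and why their defaults are what they are, what the
synthetic data generator does and does not emulate, and the numerical
conventions and known limitations.

## Time base and windowing

Everything runs at a 200 Hz working rate; `resample_record()` converts
arbitrary input rates by rational-ratio polyphase FIR resampling (the
`signal` package's near-linear-phase default design), and
`rescale_annotations()` keeps reference annotations aligned. 200 Hz
retains the full QRS energy band while keeping the arithmetic cheap.

Records are analyzed in consecutive non-overlapping 5-minute windows
(`slice_windows()`), the unit at which the AF decision is made. A final
partial window is kept — flagged — when it is at least 60 s long, and
dropped otherwise: below roughly a minute the RR series is too short for
a meaningful entropy estimate, so nothing useful could be decided on it.
Both constants are exposed (`window_s`, `min_partial_s`). Sample indices
are 0-based and episodes are half-open `[start, end)` throughout, which
makes duration arithmetic exact and unambiguous.

## QRS detection

`detect_qrs()` is a Hamilton-style energy detector: 8–16 Hz Butterworth
band-pass (zero-phase, so fiducials do not shift), 5-point derivative,
rectification, 80 ms moving-window integration, then peak classification
with an adaptive threshold placed at

```
threshold = npk + 0.3125 * (qpk - npk)
```

where `qpk` and `npk` are running means of the last 8 QRS and noise peak
heights. A 200 ms refractory period suppresses double-fires; a candidate
within 360 ms of the previous beat whose maximum slope is below half the
previous QRS's slope is rejected as a T wave; and when the gap since the
last beat exceeds 1.5× the running mean RR, the skipped peaks are
re-examined at half threshold (search-back). All constants sit in
`qrs_config()` and are the published constants of the open-source
lineage of this detector family; because every decision is relative to
running peak estimates, detection is invariant to positive rescaling of
the input, which the test suite asserts.

The R peak itself is taken as the extremum of the band-passed signal
within ±100 ms of the integration peak. On the clean synthetic templates
this lands on the true R sample exactly; on real, noisy morphology it is
accurate to a few samples.

## Per-beat features

`extract_beat_features()` measures, per beat: QRS onset and offset by
scanning outward from R until the rectified slope stays below 10% of the
beat's peak slope for 20 ms (a short 3-point derivative kernel is used
here; wider kernels systematically widen the measured duration); the P
wave as the most prominent positive deflection 40–240 ms before QRS
onset, demanding at least 0.03 mV of prominence before a P–R interval is
reported; R amplitude against the local pre-P baseline median; and the
RR neighborhood statistics `rr_mean_20`/`rr_sd_20`, pooling the RR
intervals around the 10 beats before and 10 after into a single mean and
SD (truncated at record edges). Undefined quantities — the first beat's
`rr_prev`, an undetectable P — are `NA`, never silently zero, and
classifiers treat them conservatively. The pooled single-statistic
reading of the neighborhood was chosen over separate before/after
statistics to keep the feature vector at seven inputs; the alternative
is a trivial extension.

## The VPC rule

A beat is labeled V when it is simultaneously *wide* —
`qrs_duration > 1.5 ×` the running median QRS duration of up to 50
surrounding beats — and *premature* — `rr_prev < 0.85 × rr_mean_20`.
Both factors are configurable. Beats with any undefined feature are
never labeled V: a missed V costs less downstream than a spurious one,
because V labels drive the RR correction feeding the AF stage.

## AF from RR symbolic dynamics

AF is irregularly irregular: the RR series loses the short-range
predictability of sinus rhythm. The window pipeline is:

1. `correct_rr()` — ectopy correction. Both intervals adjacent to each
   V-labeled beat are replaced by the mean of the nearest intervals on
   either side not themselves adjacent to an ectopic beat (single
   neighbor at edges; unchanged, with a warning, if every interval is
   adjacent to ectopy). VPC coupling intervals and compensatory pauses
   otherwise mimic AF irregularity.
2. `rr_to_hr()` — instantaneous rate, `hr = 60 / rr` (bpm).
3. `symbolize()` — 5 bpm quantization saturating at the top bin:
   `sy = 63` if `hr >= 315`, else `floor(hr / 5)`. The 64-symbol
   alphabet covers the physiological range; saturation caps artifacts.
4. `word_values()` — each overlapping symbol triple becomes
   `wv = sy[n-2]*2^12 + sy[n-1]*2^6 + sy[n]`, an injective base-64 code
   in 0..262143. A word summarizes three consecutive rates, so the word
   *sequence* carries short-range RR dynamics.
5. `sample_entropy()` — SampEn(m, r) of the word sequence:
   `-ln(A/B)` with `B` the number of distinct length-`m` template pairs
   within Chebyshev tolerance `r` and `A` the same for length `m+1`,
   both over the first `N − m` templates. `A = 0` or `B = 0` gives an
   explicitly undefined result (`NA`), never 0. A constant word
   sequence is entropy 0 by convention (every template matches).

Defaults `m = 2`, `r = 0.2 × SD(wv)` are the conventional SampEn
parameterization for short physiological series. The decision threshold
θ_AF = 1.22 was calibrated once, before any acceptance test ran, as the
midpoint of the gap between 20 synthetic AF windows (minimum SampEn
1.62) and 20 sinus windows (maximum 0.83) under the generator's default
laws (`scripts/calibrate_af.R`); it is stored in `af_config()` and was
not revisited. Windows with fewer than 100 beats, or with undefined
entropy, return an *undetermined* decision rather than a guess.
Consecutive AF-positive windows merge into episodes on window
boundaries; window granularity is the resolution limit of this design.

## VF from periodogram band peaks

VF is a quasi-sinusoidal oscillation with a dominant frequency of a few
Hz and no discrete QRS complexes, so it is detected on the raw signal,
not on beats. Each 5-minute window is cut into 150 non-overlapping 2-s
segments (400 samples; short enough that mixed rhythms within a segment
are rare). Per segment, after mean removal, the raw rectangular-window
periodogram `|FFT|^2 / n` is computed — no taper and no zero padding, so
the bin spacing is exactly 0.5 Hz and band membership is decided on
exact bin frequencies. The peak (maximum single-bin) power is taken in
the VF band [2.61, 4.95] Hz — in practice the bins 3.0–4.5 Hz — and the
two flanking bands (0.5, 2.61) and (4.95, 10] Hz, and the segment is VF
when

```
p_vf / (p_nVF + p_nVF2) >= 3.96
```

with the tie inclusive. "Peak" rather than band energy follows the
dominant-frequency tradition of spectral VF detection. Two numerical
conventions matter: a zero denominator with positive VF-band power is
VF (the ratio is +Inf), an all-zero spectrum is not; and band peaks
below 10⁻⁹ of the largest non-DC bin are clamped to zero, so that
machine-precision leakage from a tone outside every band cannot
manufacture a ratio. Consecutive VF segments merge into episodes, and a
single negative segment between positives is bridged
(`bridge_gaps = 1`), because episode-level scoring is badly fragmented
by isolated dropouts; set it to 0 to score raw segment decisions.

## The APC perceptron

APC beats differ from sinus beats subtly (early P, short coupling,
normal QRS), so the rule-based approach used for VPC is replaced by a
small discriminative model: a single-hidden-layer perceptron (10 hidden
units, sigmoid activations throughout) over the seven features above.
Training (`train_apc_mlp()`) imputes missing values with training-set
medians, z-scores with training-set statistics (both stored in the
model), splits 60/20/20 stratified by class, and runs full-batch
gradient descent with momentum (learning rate 0.5, momentum 0.9, at
most 500 epochs) on inverse-class-frequency-weighted cross-entropy,
early-stopping when validation loss stalls for 20 epochs and keeping
the best-validation weights. Plain batch descent at a small learning
rate converges too slowly for practical use, hence the momentum
default; with momentum disabled the training loss is provably
non-increasing at small rates, which a test asserts. Everything is
deterministic given the seed, the analytic gradients are verified
against central finite differences, and a tie at probability 0.5 labels
S (sensitivity-favoring). V labels from the upstream rule are never
overwritten. Class weighting matters because ectopy prevalence in
realistic data is a few percent.

## Integration order and the VF override

`run_pipeline()` fixes the stage order: beats → VPC → AF (on corrected
RR) → APC → VF (on raw segments) → episode assembly. AF and VF are
computed on disjoint representations and cannot see each other, so a VF
passage full of large oscillations is also, inevitably, full of
spurious "wide premature beats". With `vf_override = TRUE` (default),
beats inside detected VF episodes have V labels cleared to Q and carry
an override flag — VF is the clinically dominant call there, and
ectopic labels inside it are artifacts. Disable the flag to study the
uncorrected interaction.

## EC57-style scoring

`match_beats()` pairs reference and test beats greedily by increasing
time difference, one-to-one, within 150 ms (the conventional match
window; configurable), then counts TP/FP/FN/TN for the target class.
`episode_duration_stats()` scores rhythm episodes: ESe and E+P count
episodes touched by any overlap; DSe and D+P compare total overlapped
duration against total reference and test duration. Any-overlap is a
simplification of the standard's refined AF episode rules
(minimum-overlap requirements are not replicated), and the FPR
denominator is `fp + tn` over matched pairs. Undefined statistics
(zero denominators) are `NA`, excluded from averages, never
zero-filled. `ec57_aggregate()` provides gross (pool counts, then
divide) and average (mean of per-record statistics) modes; the two
disagree exactly when record difficulty varies, which is why both are
reported. Semantics follow the standard's intent; bit-compatibility
with the reference scoring binaries' shift heuristics is a non-goal.

## The synthetic generator

`synth_record()` emulates a patient simulator: beats are sums of
Gaussian P/Q/R/S/T waves on a rhythm plan of SINUS/AF/VF segments.
Sinus RR is 60/70 bpm ± 30 ms jitter; APCs arrive 30% early with a
sharpened early P; VPCs arrive 40% early, wide (R sd 24 ms vs 11 ms),
P-less, with a full compensatory pause; AF draws RR i.i.d. uniform
(0.35, 1.0) s — the irregularly-irregular limit — with P waves replaced
by 4–9 Hz fibrillatory wavelets; VF is a sinusoid whose instantaneous
frequency follows a mean-reverting (Ornstein–Uhlenbeck) walk clipped to
3–5 Hz, amplitude-modulated ±30%, with no annotated beats. Optional
white noise at a configured SNR, sub-0.5 Hz baseline wander and mains
tones are available. Ground-truth beat marks are exactly the rendered
R-peak samples, and episodes are exactly the plan segments.

What this does *not* emulate: real P/QRS/T morphology variation between
and within subjects, electrode motion artifacts with QRS-like spectra,
atrial flutter and other organized supraventricular rhythms,
polymorphic VF onset, and the annotation ambiguity of human reference
labels. Tests passing on this corpus therefore demonstrate algorithmic
correctness and self-consistency — the stated rules, faithfully
computed — not clinical-grade performance on database records, which is
known from the literature on this algorithm family to be substantially
harder (the worked example in the README already shows the VPC rule
over-triggering inside AF).

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` use: 10 records × 10 min for
QRS scoring; 20 + 20 five-minute windows for the AF threshold check
(disjoint seeds from the 20 + 20 used for calibration); 100 random
sequences of 50–500 points against a brute-force SampEn counter (1e-12
agreement); 1000 random episode configurations against a per-sample
overlap counter; and a 10-record, 15-minute corpus with planted AF and
VF blocks for end-to-end episode recovery. Every stochastic quantity is
seeded; pipelines are deterministic functions of (record, config,
seed).

## Known limitations

* AF decisions have 5-minute granularity; brief paroxysms inside a
  mostly-sinus window are diluted below threshold.
* The AF threshold is calibrated on synthetic RR laws; porting to a new
  population should re-run `calibrate-af` on representative windows.
* The VF band ratio sees any strong 3–4.5 Hz narrowband artifact
  (e.g. some motion artifacts) as VF; upstream signal-quality gating is
  out of scope here.
* The APC stage's reported numbers depend on a trained model; no
  pretrained clinical model ships with the package.
* Resampling phase is not exactly zero, so beat fiducials on resampled
  records can shift by a sample or two relative to annotations rescaled
  by pure index arithmetic — well inside the 150 ms match window.
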