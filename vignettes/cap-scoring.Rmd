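---
title: "Scoring the cyclic alternating pattern: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the cyclic alternating pattern: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scoring problem

The cyclic alternating pattern (CAP) of NREM sleep alternates transient
activations (A-phases, 2–60 s) with background (B-phases) at up to
one-minute intervals. Subtypes differ spectrally: A1 is a delta-band
amplitude excursion of at least a third over background, A3 is a fast
low-voltage rhythm, and A2 mixes both, the A1-like part covering 50–80% of
the event. `capscore` scores every second of a single monopolar EEG channel
as B, A1, A2 or A3 (or just A vs B), using a fixed feature bank, per-subject
conditioning, fold-wise feature reduction, one of four classifier families,
a duration post-filter and leave-one-subject-out (LOSO) evaluation.

The core assumption is that one second is the scoring unit: every feature
is defined so that it emits exactly one value per second regardless of the
native sampling rate (128–512 Hz supported), and labels discretise
annotation intervals to the same 1 Hz grid using majority overlap within
half-open epochs `[t, t+1)` (0-based). The discretisation rule is ours, not
part of the scoring tradition: majority overlap, an exact tie between an
A subtype and background resolved toward the A subtype (the minority class
must not be eroded at boundaries), and overlapping events resolved by
later-onset-wins, which is deterministic once events are sorted.

## Filtering

Each recording is decomposed with causal third-order band-pass Butterworth
filters into the broadband signal (0.3–35 Hz) and the delta (0.3–4),
theta (4–8), alpha (8–13), sigma (13–16) and beta (16–35 Hz) bands.
Filtering is **single-pass causal**, not zero-phase forward–backward: the
amplitude features are explicitly trailing-window ("past samples")
quantities, so the whole chain stays causal and the small phase delay is
accepted. The third-order design is realised as a cascade of biquad
sections (each an `(1 − z⁻²)` zero pair over a conjugate pole pair) rather
than a direct-form order-6 transfer function, which is numerically
ill-conditioned for a 0.3 Hz edge at 512 Hz. No resampling is performed at
any point.

## The 55 features

Per second, the bank produces: `MMSD_φ`, `C_{φ,τ}`, `C_{φ,τ0}` and `TEO_φ`
over the five sub-bands; `ZCR_φ`, `LZC_φ` and variance `s²_φ` over all six
bands; `Max_freq`, `Mean_freq`, `Spec_area` from a short-time Fourier
transform of the broadband signal; `EMD_1..12`; `ShEnt`; and `FD` — 55 in
total. Parameters that matter:

* **Amplitude windows** `τ = 60 s`, `τ0 = 2 s` (trailing, steps of 1 s, i.e.
  98% and 50% overlap). `C` is the mean of the *rectified* signal — the
  amplitude estimator is not prescribed anywhere authoritative, and mean
  rectified amplitude is the convention of the detector lineage this
  descriptor comes from. Whether the window at second `t` includes the
  current second is equally unprescribed; we use a trailing window ending
  at `t + 1` s. Early seconds use a growing window (all samples so far)
  so that all 55 series share one time base; the alternative (emitting
  nothing for the first 59 s) would misalign the matrix with the labels.
* **MMSD** `= (C_{τ0} − C_τ)/C_τ`, dimensionless and scale-invariant; the
  denominator is floored at 1e-12 µV (a warning is logged) so silent
  channels cannot produce infinities.
* **TEO** is non-causal, so it is computed over the whole series first and
  segmented afterwards; each second reports its maximum TEO value.
* **ZCR** counts strict sign changes in non-overlapping 1 s epochs; a zero
  sample inherits the previous nonzero sign, and a crossing between
  samples `n` and `n+1` belongs to the epoch of `n+1`.
* **LZC** binarises each 1 s epoch at its median (the threshold rule is
  configurable) and reports the unnormalised LZ76 exhaustive-parsing
  dictionary size; a constant epoch yields complexity 2.
* **STFT** uses a trailing 3 s Hamming window (2 s overlap) covering
  `[t−2, t+1)`. `Mean_freq` ("frequency of mean energy") is ambiguous in
  the literature; we chose the spectral centroid. The median frequency
  (splitting cumulative energy in half) is a defensible alternative and
  would change only this one series.
* **EMD** is applied to the full signal (windowing first would distort the
  sifting) with classical cubic-spline envelopes, mirrored end extrema, a
  Cauchy stopping criterion of 0.2 and at most 200 sifts per mode; each of
  12 levels is averaged per second. If the signal exhausts its
  oscillations before 12 modes, the missing levels are zero-filled, so the
  feature count is stable.
* **ShEnt** uses a 16-bin equal-width histogram over each epoch's own
  range (log base 2); **FD** is Higuchi's estimator with `k_max = 8`, which
  at 128–512 samples per epoch keeps every curve-length average populated;
  a constant epoch reports FD 1 by convention. **Variance** is the unbiased
  (N−1) estimator.

Variance is computed for all six bands. A reasonable reading of the
tradition would restrict it to the broadband signal only, but the
55-feature inventory requires the six-band version and the ranked feature
lists in the literature include the per-band variances, so the six-band
reading is used.

## Conditioning

In fixed order, per feature and per subject: (1) causal moving-average
smoothing, order 30 (31 taps — "order" is the number of delays, the
standard FIR convention), applied to every feature *except* those whose
names begin with MMSD, TEO or EMD, which detect exactly the transient
changes smoothing would erase; (2) outlier replacement at 4 standard
deviations by the series median — 4 rather than the customary 3 because
A-phases are themselves large excursions; (3) min–max normalisation to
[0, 1], constants mapping to zero. The exemption list is read literally:
the raw amplitude series `C_{φ,τ}`/`C_{φ,τ0}` **are** smoothed. Whether
outlier statistics should be taken before or after smoothing is not
prescribed; the narrative order above is used. All statistics are per
subject, so conditioning cannot leak information across subjects or folds.

## Reduction and classification

mRMR ranks features greedily by mutual information with the labels minus
the mean mutual information with the already-selected set (the difference
form, MID), after tertile discretisation of each feature; ties break
toward the earlier column so the ranking is deterministic. Ranking is
recomputed on the training subjects of every fold — rankings genuinely
differ between subjects, and a single global ranking would leak held-out
information. PCA (centred, unscaled — inputs are already min–max
normalised) is the projection alternative, likewise fitted per fold.

Discriminant analysis uses closed-form Gaussian discriminants (pooled
covariance for the linear form, per-class for the quadratic) with an
always-on ridge of 1e-8 times the mean diagonal — equivalent decision
surfaces to the error-minimising formulation, far more stable, and robust
to degenerate within-class scatter. k-NN is an exact Euclidean majority
vote; vote ties go to the nearest tied class, making prediction
deterministic (off-the-shelf implementations break ties at random, which
would make LOSO results irreproducible). The SVM is one-against-all: one
soft-margin Gaussian-kernel machine per class (`exp(−γ‖xi − xj‖²)`; the
kernel exponent is negative — a positive exponent is unbounded and cannot
be meant), prediction by the largest decision value. Grid search evaluates
each `(C, γ)` pair by mean WAC over LOSO folds and breaks ties toward
smaller `C`, then smaller `γ`. Selecting the pair on the outer folds is
statistically optimistic; a nested protocol (inner LOSO on the training
subjects of each outer fold) is implemented as an option, but the default
is the outer protocol because that is what the grid-search contract itself
computes and what the reported grids in this literature mean. Kernel
solvers are quadratic in the training size, so grid search accepts a
`max_train` cap implemented as a deterministic, evenly-spaced stratified
subsample of training seconds; the final per-fold models train on all
training seconds.

## Post-processing and metrics

An A-phase must last 2–60 s, so maximal runs of consecutive A-labelled
seconds of length 1 or longer than 60 are relabelled B. Runs are defined
on the A/B collapse — the rule is only stated in A-vs-B terms — and a
surviving run keeps its per-second subtypes. The filter is idempotent.

Confusion matrices are oriented rows = predicted, columns = true.
Sensitivity and specificity are per class; accuracy is trace over total
(for two classes this equals the per-class formula); the headline metric
is the weighted accuracy `WAC = (1/K) Σ_j n_jj/n_{+,j}`, the mean
per-true-class recall, because background outnumbers A-phases several-fold
and plain accuracy rewards scoring everything as background. A class with
no true instances has undefined recall and is excluded from WAC with a
warning. Reported WAC/AC are means over folds; pooled-matrix versions are
also emitted.

## The synthetic cohort

The generator exists so that every stage is testable without clinical
recordings. Background EEG is 1/f-power noise band-limited to 0.3–35 Hz —
the minimal spectral model under which all band features take
non-degenerate values — scaled exactly to a target SD (default 25 µV, an
ordinary sleep-EEG background amplitude). A-phases are planted
non-overlapping, at least 2 s apart, integer-second aligned, with
durations drawn from a clipped gamma (mean ≈ 10 s, support 2–60 s, typical
of scored A-phases). A1 events multiply the delta component by `a1_gain`
(default 2, comfortably above the defining 4/3); A3 events add fast
8–35 Hz activity at `a3_gain` times the background fast-band amplitude
(default 2 — "low voltage" has no quantitative definition, so the fast-band
gain convention is ours) while attenuating delta; A2 applies the A1
modification over a uniform 50–80% leading fraction and the A3
modification over the rest. Default cohort: 8 subjects × 20 minutes at
128 Hz, 1.5 events/min, subtype mix 0.4/0.3/0.3, per-subject background-SD
jitter ±20%; per-subject seeds derive from one master seed. These are the
package's study conditions: small enough to run on one CPU in minutes,
large enough that LOSO estimates are meaningful.

What the generator does **not** emulate: sleep-stage architecture and
stage-dependent background drift, K-complex/spindle morphology, CAP-cycle
periodicity, artifacts (eye blinks, EMG), and non-stationary background
amplitude. Consequences worth knowing: the stationary background makes the
60 s amplitude series `C_{φ,τ}` nearly flat, so features that track slow
background modulation rank lower here than they do on clinical data, and
passing tests demonstrate *parameter recovery under the generator's
assumptions*, not clinical performance.

## Evaluation scale and a known limitation

The acceptance computations run the default cohort (9,600 scored seconds;
8 LOSO folds of 8,400 training seconds; SVM grid search on a 3×3 grid
centred on `C = 2⁻¹, γ = 2⁻¹` with `max_train = 3000`). At this training
size the 25-nearest-neighbour binary scorer under-calls the minority
class: with roughly three background seconds per A second, an A-phase
test point needs 13 of 25 neighbours from the minority class, so its
correct detections are sparse and often one second long — exactly what
the duration post-filter then removes. The binary k-NN weighted accuracy
therefore sits just below the 0.70 parameter-recovery bound that the
discriminant-analysis and SVM families clear under the identical
pipeline; the effect is a genuine interaction of k-NN majority voting,
class imbalance and the duration rule at this cohort size, not an
implementation artefact (predictions agree with an independent k-NN
implementation on the same folds). On clinical-scale data (whole nights,
tens of subjects) the neighbourhoods densify and this penalty shrinks.

## Degenerate inputs and numerical conventions

Zero or constant signals: band filters return (numerically) zero, TEO and
variance return 0, ZCR returns 0, LZC returns 2, ShEnt returns 0, FD
returns 1, STFT descriptors return 0 by convention. MMSD denominators are
floored at 1e-12 µV. Min–max normalisation maps constant series to zero.
The EDF writer quantises to 16 bits; round-trip error is bounded by the
physical range over 32767.
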