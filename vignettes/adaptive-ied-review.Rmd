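---
title: "Adaptive template-based IED detection and review"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive template-based IED detection and review}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Interictal epileptiform discharges (IEDs) — spikes, sharp waves and
spike-and-slow-wave complexes between seizures — are the marker an
electroencephalographer looks for when diagnosing epilepsy from a routine
scalp EEG. Fully automated spike detectors must pick an operating point on
a sensitivity / false-positive-rate curve, and at clinically acceptable
false-positive rates they miss too much. `iedreview` implements a different
compromise: detection applies essentially *no* specificity threshold beyond
a correlation floor, and the burden of rejecting false positives is moved
into an interactive review that is made cheap by ranking candidates well
and by learning from every answer the reviewer gives.

The model has three parts.

**Template matching.** Every template is one annotated spike-wave epoch
(0.212–0.860 s, one channel, one montage, 100 Hz). The match between a
template $t$ and a signal window starting at sample $i$ is the Pearson
correlation $c_i$; windows with $c_i > 0.85$ (strict) at a local maximum of
the correlation trace are candidates. Non-maximum suppression over one
template length keeps a single candidate per underlying event per template.
Each template additionally carries a property gate and a linear SVM over
four match features — correlation, matching variance (residual variance
after least-squares scaling of the template onto the epoch), absolute
peak-to-peak amplitude difference, and the ratio of epoch RMS to the RMS of
the preceding second — trained during database construction where every
supra-threshold detection has a known truth label.

**Certainty and reliability.** A template's reliability is its lifetime
fraction of true adjudicated detections, $r = T/(T+F)$. Nominations merge
into groups (see below), and a group's certainty aggregates its members'
evidence as a noisy-OR, $g = 1 - \prod_i (1 - c_i r_i)$, with $c_i$ clamped
to $[0,1]$. The published description states the two ingredients
(correlation, reliability) but the exact aggregation formula is in a
supplement that is not available; noisy-OR was adopted because it is
bounded in $[0,1]$, uses exactly those two factors, is monotone in both
(more corroboration and more reliable templates never lower certainty), and
treats members as independent evidence. The aggregator is pluggable
(`noisy_or`, `mean`, `max`) so a different formula can be substituted
without touching the review machinery.

**Adaptive review.** Batches of the ten most certain pending groups are
presented; each receives confirm / reject / unsure. Confirm adds one true
count per member nomination to that member's template, reject one false
count, unsure nothing — per-detection counting, chosen because it matches
how the counts accumulate in training (one label per detection). Effective
reliabilities are recomputed session-locally and the remaining pool is
re-ranked. The persistent database is only updated at `finalize_review()`,
so an abandoned session has no global side effects.

# Grouping rules and tie-breaking

Grouping happens in a fixed order: (1) same-channel single-linkage merging
of nominations whose intervals overlap by *more than* 75% of the shorter
interval; (2) discard of merged groups with fewer than three member
nominations; (3) cross-channel merging of the survivors whose onsets start
strictly within one second of the earliest (seed) group's onset. The
denominator of the overlap fraction (shorter interval), the strictness of
both inequalities, the use of single linkage, and the placement of the
three-member filter *before* the cross-channel step are all implementation
decisions; the source description fixes only the three constants (75%,
three, one second) and the step order. Intervals are half-open
`[start, end)` in samples at 100 Hz throughout, which makes ties exact and
grouping permutation-invariant; batch ordering ties are broken by earlier
onset, then lexicographic group id, so sessions replay identically.

# Preprocessing and montages

Recordings are band-pass filtered 0.5–30 Hz with a 4th-order Butterworth
applied forward–backward (zero phase, so event onsets coincide across
montages) and resampled to 100 Hz. Zero-phase IIR filtering is a choice —
only the band edges are prescribed — and a twice-filtered signal is not
bit-identical to a once-filtered one: near the 30 Hz edge the second pass
removes a relative $\sim 10^{-4}$ of the amplitude; the test suite checks
near-idempotence at $10^{-2}$ relative RMS on mid-band content rather than
exact idempotence. The three review montages are the identity (common
reference), the longitudinal double-banana bipolar chain, and a Laplacian
(electrode minus the mean of its 10–20 neighbours). The bipolar chain and
the neighbour table are not prescribed anywhere; the package ships a
standard set in `inst/extdata/montages.yaml` as editable configuration.
Eye-blink artifact reduction by independent component analysis is not
implemented: the synthetic data contain no blinks, and the filter chain is
orthogonal to the contribution of the method.

# The synthetic data generator

The clinical training (8 EEGs, 175 min, 482 events) and evaluation
(15 EEGs, 306 min, 241 IEDs) recordings behind the method were never
deposited, so the package generates its own study data. The generator
emulates the properties the pipeline actually depends on:

* 19-channel 10–20 background at 100 Hz: 1/f-weighted noise
  (10–30 µV RMS), a posterior-dominant 8–12 Hz rhythm with a slowly
  wandering envelope on occipital/parietal channels, and a slow
  multiplicative gain drift (~0.1 Hz) so that the preceding-background
  feature is informative;
* spike-wave families: a difference-of-Gaussians transient (35–60 ms)
  followed by a skewable half-sine slow wave, 0.30–0.70 s, 100–160 µV
  peak, predominantly surface-negative, localized on a pair of adjacent
  anterior electrodes with 0.3–0.5 attenuated spread to their 10–20
  neighbours;
* events injected at 1/min on a jittered regular grid (±25% amplitude,
  ±8% duration per event), with exact ground truth returned.

Default scale is 3 training and 3 evaluation recordings of 5 minutes each
with 4 families — small enough that the complete
train/detect/review cycle runs in minutes on one core, large enough that
every stage (multi-channel spread, cross-montage detection, grouping,
ranked review) is exercised. Training marks carry channel labels for every
channel where the discharge is visible (focus plus spread), mirroring
channel-level training annotation practice; evaluation marks carry onset
and duration only, mirroring evaluation-style marks, and the simulated
reviewer accordingly confirms on temporal overlap alone.

What the generator deliberately does *not* model: eye-blink/EMG/movement
artifacts, electrode pops, sleep architecture, and pathological background
rhythms. Real EEG produces far more supra-threshold false candidates than
this clean background does, so the synthetic false-positive rates and the
near-perfect early recall here say that the machinery is correct, not that
clinical performance would match. The published clinical numbers (a third
of events after one iteration, 95% after fifteen; 0.24–6.6 false positives
per minute) were measured on undeposited hospital recordings and are not
reproducible at desk scale; the package's acceptance checks are therefore
property-based (oracle equivalence, rule fidelity, bookkeeping
conservation, ranking dominance over a random baseline) rather than
number-matching.

# Numerical and training choices

* **FFT correlation.** The numerator is a circular FFT cross-correlation
  (signal padded to the next highly composite length); window means and
  variances come from running sums. Windows whose variance falls below
  `1e-12 · m · max(Σx², 1)` are treated as flat and get correlation 0.
  Agreement with a per-window loop is ~1e-15 in practice; the test bound is
  1e-9.
* **Threshold.** `c > 0.85` strict, applied to the signed correlation; a
  perfectly anti-correlated waveform never nominates. No smoothing is
  applied to the trace before peak picking.
* **Per-template SVM.** `e1071::svm`, linear kernel, cost 1, class weights
  inversely proportional to class frequency, on features standardized by
  training mean/sd. The weight vector and bias are extracted and stored, so
  a saved database is self-contained. Templates whose training detections
  are single-class get a trivial accept (all true) or reject (all false —
  subsequently pruned) rule.
* **Property bounds.** Per-feature `[min, max]` over true training
  detections, each side widened by 10% of the observed width (a
  zero-width interval is padded by 10% of its magnitude). Applied as a
  hard gate before the classifier.
* **Pruning.** Discards templates with no detections, only false
  detections, or fewer than `min_true = 2` true detections with no false
  ones. Every survivor has $T+F \ge 1$, so $r$ is always defined; an
  optional Laplace-smoothed form $(T+1)/(T+F+2)$ is available (off by
  default) for workflows that want shrinkage toward 0.5 at low counts.
* **Reliability formula.** $T/(T+F)$ is the simplest ratio consistent with
  "number of true and false predictions made over all time"; the original
  formula appears only as an inaccessible image.
* **Persistence.** The database is one versioned JSON file written at full
  numeric precision; a wrong version or corrupted file is an explicit
  error.
* **Determinism.** Every stochastic step (generator, random-order baseline)
  takes an explicit seed and restores the caller's RNG state; detection and
  training are seed-free deterministic, and `detect_ieds()` output is
  sorted by (montage, channel, start, template id) regardless of internal
  iteration order.

# Evaluation harness

`simulate_review()` replays a session with an automatic reviewer that
confirms any presented group overlapping a ground-truth event. Recall is
reported against *detectable* truth events (those overlapped by at least
one group in the initial pool), which separates ranking quality from
detector sensitivity. The random-order baseline presents uniformly random
pending batches with the same confirm rule; comparing
iterations-to-recall between the two isolates the value of
certainty ranking. At the default scale the per-recording candidate pools
are small and clean, so both policies converge quickly; the certainty
policy must merely never be slower on average (over 20 baseline seeds) —
on noisier data the gap widens, which is the regime the clinical
evaluation addressed.

`scripts/acceptance.R` runs the whole chain end-to-end (problem sizes: 100
random correlation pairs; 3 + 3 recordings of 5 min; 20 baseline seeds)
and writes every computed quantity as JSON.

# Known limitations

* The certainty formula and the exact match-feature definitions of the
  original system live in sources that are not available; the
  implementations here are documented stand-ins behind stable interfaces.
* "Unsure" outcomes contribute no reliability information and are excluded
  from the exported annotations; whether the original system treated them
  differently is unknown.
* Templates are never *added* from confirmed events during review — the
  database only re-weights; closed-loop template harvesting is explicitly
  out of scope.
* The EDF layer writes plain EDF (no EDF+ annotation embedding), 16-bit
  quantized with per-channel symmetric physical ranges.
* Synthetic backgrounds are artifact-free; false-positive statistics do not
  transfer to clinical data.
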