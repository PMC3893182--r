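# iedreview

Self-adapting detection and iterative review of interictal epileptiform
discharges (IEDs) in multichannel scalp EEG.

Routine 20–30 minute scalp EEG is the standard diagnostic procedure for
epilepsy, and the diagnostic marker is the IED: a spike, sharp wave,
poly-spike or spike-and-slow-wave transient between seizures. Automated
spike detectors force a threshold trade-off — high sensitivity with many
false positives, or few false positives with missed events. `iedreview`
implements an alternative working model for clinical neurophysiologists and
EEG-methods researchers: detect *everything* that resembles a template
waveform, rank the candidates by a certainty value, and let an iterative
review loop absorb reviewer feedback so that the most trustworthy
candidates surface first and the system keeps learning across recordings.

## The method

**Detection.** A database of template waveforms (0.212–0.860 s epochs cut
from annotated training EEG, one per event × channel × montage) is slid
over every channel of a new recording in three montages (common reference,
longitudinal bipolar, Laplacian). The sliding Pearson correlation

```
c_i = corr(template, signal[i : i+m))
```

is computed by FFT cross-correlation with running-sum normalization.
Positions with `c > 0.85` that also satisfy the template's learned property
bounds and its per-template linear SVM (features: correlation, matching
variance, amplitude difference, background ratio) become *nominations*.
Each nomination carries the template's reliability

```
r = T / (T + F)
```

where `T` and `F` are the template's lifetime true/false adjudicated
detections.

**Grouping.** Same-channel nominations overlapping by more than 75% (of the
shorter interval) merge; merged groups with fewer than three members are
discarded; groups whose onsets fall within one second merge across
channels. Each group gets a certainty by noisy-OR aggregation:

```
g = 1 − Π_i (1 − c_i · r_i)
```

**Review.** The ten most certain pending groups are presented per
iteration. Confirmations/rejections add per-detection true/false counts for
the contributing templates, session-local reliabilities are recomputed, and
the remaining pool is re-ranked before the next iteration. On finalize the
accumulated counts update the persistent database — the global update that
makes the system improve with use.

Because no clinical recordings ship with the package, a seeded synthetic
generator produces 19-channel 10–20 EEG background (1/f noise, posterior
8–12 Hz rhythm, slow gain drift) with injected spike-wave discharges and
exact ground truth, at a desk-scale default of 3 training + 3 evaluation
recordings of 5 minutes each.

## Worked example

```r
library(iedreview)

ds   <- make_dataset(dataset_spec(), seed = 101)
tpls <- extract_templates(ds$training$recordings, ds$training$annotations)
db   <- prune_templates(train_templates(tpls, ds$training$recordings,
                                        ds$training$annotations))
glance(db)
#> # A tibble: 1 × 5
#>   n_templates n_montages total_true total_false mean_reliability
#>         <int>      <int>      <int>       <int>            <dbl>
#> 1          80          3       1267           9            0.952

rec    <- ds$evaluation$recordings[[1]]
truth  <- dplyr::filter(ds$evaluation$truth, recording_id == rec$recording_id)
noms   <- detect_ieds(rec, db)
groups <- group_nominations(noms, db)
sim    <- simulate_review(start_review(groups, db), truth)
sim$curve[1, c("iteration", "n_presented", "truth_confirmed", "recall")]
#> # A tibble: 1 × 4
#>   iteration n_presented truth_confirmed recall
#>       <int>       <int>           <int>  <dbl>
#> 1         1           5               5      1
```

365 templates are extracted from the training marks; 80 survive pruning
(the rest never detected anything, detected only false events, or made too
few correct detections to be informative). On the first evaluation
recording all five injected discharges are nominated, grouped, and — being
the most certain groups in the pool — confirmed within the first review
iteration. `autoplot(sim$curve)` draws the recall-by-iteration curve, and
`finalize_review(sim$session, db)` exports the confirmed annotations and
writes the feedback back into the template counts.

A command-line interface wraps the same pipeline
(`exec/ied synth|train|detect|review`, see `?ied_main`).

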