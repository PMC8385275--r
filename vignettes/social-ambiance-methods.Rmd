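---
title: "Measuring social ambiance from wearable audio: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring social ambiance from wearable audio: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sambiance)
```

## The measure

`sambiance` estimates the *social ambiance* around a wearer of a wrist audio
band: a proxy for how socially rich their environment is, derived from the
number of people speaking simultaneously nearby. Privacy is structural
rather than procedural — the pipeline never transcribes, stores or models
speech content; it only maps each 5-second window to one of four
concurrent-speaker classes:

* **AL-0** — no speech detected,
* **AL-1** — one speaker (talking to oneself, a phone call, one person close by),
* **AL-2** — 2–5 simultaneous speakers (a medium group),
* **AL-3** — more than 5 (a large group).

The coarse bins mirror human perception: people judge the size of small
groups far better than large ones, so resolution is spent where perception
has it. A participant-day is summarized by the percentage of recorded time
at each level, `p0..p3`, plus the Shannon entropy
`H = -sum(p_i * log(p_i))` with `p_i` the level proportions — `H = 0` for a
day spent entirely at one level, `H = log(4)` for a day spread evenly across
all four. Daily vectors are averaged into a weekly per-participant SAM
vector.

Two aggregation choices are deliberate and configurable:

* **Equal day weights.** `weekly_sam()` weights each available day equally
  regardless of how many hours were recorded that day;
  `weight_by_time = TRUE` switches to pooling windows. Equal weighting keeps
  a long Saturday from dominating the week; the coverage fields
  (`days_used`, `total_recorded`) let users filter thin days instead.
* **Denominator is recorded time**, not the nominal wear protocol. Coverage
  is reported so low-coverage days are visible rather than silently diluted.
* TV and radio speech is *not* filtered out: distinguishing broadcast from
  in-person voices without content analysis is an open problem, so the
  measure is explicitly "speech in the environment", whatever its source.
* Entropy is reported in nats (`base = exp(1)`); `base = 2` gives bits.

## The counting model

The estimator follows the x-vector speaker-embedding recipe at desk scale:

1. **Features** (25 ms frames, 10 ms hop): 40 log-mel filterbank energies
   (unit-area filters, per-clip mean normalization), an autocorrelation
   pitch track limited to 60–400 Hz, the pitch salience (normalized
   autocorrelation peak), and a voicing flag.
2. **Frame-level layers**: three ReLU layers over spliced context
   (±2, then {−2,0,+2}, then {−3,0,+3} frames), width 96 — the time-dilated
   part of the network.
3. **Statistics pooling**: per-dimension mean and standard deviation over
   the window's frames, turning a variable-length sequence into a fixed
   192-vector. Overlapping speech changes exactly these statistics — more
   simultaneous voices raise spectral density and change frame-to-frame
   variability — which is why the pooled representation can count without
   separating speakers.
4. **Segment level**: a rectified 128-dimensional embedding layer, then a
   4-class softmax head used for training (cross-entropy, Adam with a
   0.9-per-epoch learning-rate decay, ~101k parameters in total).
5. **Backend**: after training, embeddings are length-normalized — the
   usual preparation before cosine scoring of x-vector-style embeddings —
   and each class keeps the mean normalized training embedding as its
   centroid; a new window is assigned the class with the smallest cosine
   distance. Exact ties resolve toward the *lower* class — the
   conservative direction for an ambiance measure. A direct softmax-argmax
   backend is provided for comparison
   (`counter_config(backend = "softmax")`).

Classes are trained directly as the four perceptual bins rather than exact
counts that are binned afterwards: the bins are the measure's native
resolution, and training at that resolution spends model capacity where it
matters.

Training is fully seeded: corpus seed, initialization seed and shuffling
seeds determine every weight, so a rerun reproduces the model bit for bit.

## The synthetic corpus

No public speech corpus is downloaded; the generator produces everything,
which keeps model development reproducible and content-free:

* **Voices** are glottal-like harmonic stacks (f0 ∈ [80, 350] Hz with slow
  vibrato and drift) shaped by three formant resonances and gated into
  syllables (brief ≤ 30 ms inter-syllable dips; phrase-level pauses come
  from a separate burst/pause activity pattern of 2–8 s bursts and 0.5–4 s
  pauses). Each speaker gets a volume factor in [−3, +3] dB and a tempo
  factor in [0.9, 1.25]. The tempo range is our reading of a speaking-rate
  augmentation whose published units were ambiguous; it is configurable.
* **Noise** comes in three categories — tonal beeps/clicks ("things"),
  slowly modulated broadband noise ("natural"), sustained non-vocal chords
  ("music") — mixed at an SNR drawn from [0, 20] dB by default (the easy
  training regime narrows this to [15, 30] dB), with powers measured on
  speech-active portions only.
* **Reverberation** uses exponentially decaying Gaussian-noise impulse
  responses whose Schroeder backward integral decays 60 dB over RT60;
  RT60 is drawn from [0.1, 1.0] s by default ([0, 0.3] s in the easy
  regime).
* **Labels**: a window's true count is the number of speakers whose
  activity covers at least half (2.5 s) of it; partial-window speech
  below that threshold does not count. Labels therefore derive from the
  activity pattern (bursts), not the syllable gate.
* **Splits**: voice seeds are drawn from disjoint pools per
  train/validation/test split, so evaluation on the test split is always
  an unseen-speaker evaluation by construction.

What the generator does *not* emulate: real phonetic content, vocal music,
moving sources, overlapping noise categories, device transfer functions, or
the long-tailed loudness statistics of free-living audio. Tests passing on
this corpus demonstrate that the pipeline's machinery is correct and that
the architecture can learn concurrent-speaker texture; they do not certify
field accuracy on real recordings, which requires the real corpora and the
full-size model.

## Voice activity detection

The VAD is a classical two-feature detector: a frame is voiced when
(a) its log energy exceeds the clip's noise floor (10th percentile of frame
log-energies, bounded below at −75 dB so digital silence stays unvoiced) by
at least 10 dB, and (b) its spectral flatness below 4 kHz is under 0.4.
A hangover keeps a frame voiced for up to 3 frames after the raw decision
drops, bridging brief intra-word dips. The floor percentile matters: clips
with near-continuous speech must keep their floor in the pauses, which is
why it sits at the 10th rather than a higher percentile. Because all
thresholds are relative to the clip, a uniform gain change cannot reduce
the voiced count. The thresholds were calibrated on the synthetic corpus to
detect ≥ 80% of in-burst frames of a single speaker at 20 dB SNR while
flagging < 20% of natural-noise frames; all of them are arguments of
`detect_voice()`.

## Statistics layer

Group contrasts use classical one-way ANOVA; the package reports both the
overall three-group test and pairwise two-group contrasts of each patient
group against the reference group, matching the common reporting style for
time-budget measures. Associations are per-group Gaussian GLMs (identity
link) of one self-report outcome on one ambiance measure at a time — the
simplest model consistent with a t-statistic grid of measure × outcome ×
group — and the Benjamini–Hochberg step-up procedure adjusts p-values, by
default across the full 5 × 8 × 3 = 120-test grid (per-group families are
available via `fdr_family = "group"`). Significance tiers are reported at
FDR < 0.1 / 0.05 / 0.01.

`generate_cohort()` simulates the study's data shape: three groups of
(13, 11, 8) participants by default, per-participant SAM fractions drawn
from a Dirichlet distribution around group mean profiles (concentration 30,
so fractions vary by several percentage points between individuals), and
outcomes as group baselines plus optional linear effects of the SAM
measures plus Gaussian noise. The default group profiles encode the
qualitative pattern motivating the measure — controls spend more time at
moderate/high ambiance, patient groups more time in quiet — and the default
outcome baselines use published group means where available (e.g. PHQ-9 and
GAD-7 group averages); default effect sizes are zero so that association
analyses on a default cohort are null. These defaults were chosen once as
the simulation conditions and are all overridable arguments.

## Phone-call context

Remote interaction is quantified from call logs whose numbers are replaced
by MD5 digests. Plain MD5 over the small space of phone numbers is
reversible by enumeration; `hash_number()` reproduces that procedure
faithfully but accepts an optional salt for a keyed variant. Daily
incoming/outgoing durations attribute midnight-spanning calls to their
start day. `phone_fraction()` intersects call intervals with recording
sessions on half-open intervals after merging overlaps, so it is invariant
to splitting a call into contiguous records. Whether call-overlapping
windows are excluded from the SAM or only quantified as context is a flag
(`mask_call_windows()` / `flags$mask_phone_windows`), since both analyses
are defensible.

## Numerical choices and degenerate inputs

* Entropy uses `0 * log 0 := 0`; profiles must sum to 100 within 1e-6.
* Empty participant-days are rejected (and should be excluded and logged
  upstream), not silently imputed.
* `score_count()` refuses zero-norm embeddings; statistics pooling guards
  zero variance with an epsilon (1e-8), so constant windows embed cleanly.
* A mixture with no speech and finite SNR has no reference power; noise is
  then set to a fixed ambient RMS (0.05) rather than rejected.
* Count classes absent from an evaluation split keep their row with `NA`
  sensitivity; a class absent from a *training* split is an error.
* All seeds below 2^31; every seeded stream is derived from a master seed
  with a hash, so stages are independent and reproducible.

## Problem sizes used in the shipped checks

The package's own test material uses a 40-example corpus for mechanical
checks and a 500-mixture easy-regime corpus (70/15/15 split, 12 training
epochs) for the learning checks — the scale at which the ~100k-parameter
model trains comfortably on a single CPU. At that scale the counter
reaches macro sensitivity/specificity well above 75% on held-out data and
loses only a few points on unseen-speaker test material; the full-size
result on real corpora is out of this package's scope.

## Known limitations

* Synthetic voices share one production model; real inter-speaker
  variability is far larger, and real "> 5 speakers" scenes include crowd
  babble that this generator only approximates as superposition.
* The VAD is classical (energy + flatness); a neural VAD would be more
  robust at low SNR but is out of scope here.
* Exact counts above 5 are never estimated — by design, the measure's top
  bin is open-ended.
* The association layer models one predictor at a time without covariate
  adjustment; with ~10 participants per group, richer models would overfit.
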