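---
title: "Methods: extraction, statistics, adjudication, and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extraction, statistics, adjudication, and the synthetic cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents what `robustmark` computes and why: the signal
processing behind the acoustic biomarkers, the transcript conventions behind
the linguistic and cognitive biomarkers, the statistical conventions, the
robustness adjudication semantics, and the generative model of the synthetic
cohort generator — including its deliberate simplifications and the problem
sizes it is intended for.

## 1. Pre-processing

All extraction operates on mono waveforms at 16 kHz.

* **Resampling** (`resample_wave()`): band-limited rational-ratio resampling
  (via the `signal` package) after reducing the ratio by the GCD of the two
  rates; output length is fixed to `round(n * new_rate / old_rate)`.
* **Loudness normalization** (`normalize_loudness()`): a simplified
  integrated loudness — the energy-weighted mean level of 400 ms frames
  (100 ms hop) that lie within 40 dB of the loudest frame — is scaled to a
  −23 dBFS target. This is a single-gate approximation of broadcast-style
  loudness normalization: no spectral pre-filter, no second absolute gate.
  It is scale-invariant and idempotent, which is all that downstream
  intensity variability requires; only the intensity contour is affected,
  because pitch, formant, and pause extraction are level-free.
* **Utterance concatenation** (`concatenate_tdu()`): cohorts that elicit
  several short text-dependent utterances per speaker are analyzed
  speaker-wise. Each recording has its edge silences trimmed (energy VAD
  with a 50 ms margin) before concatenation, so the spliced pauses are not
  inflated by leading/trailing room tone. Word time anchors of concatenated
  transcripts are shifted by the durations of the preceding recordings.

## 2. Acoustic biomarkers

Three contour variabilities and six pause statistics, all per recording.

**F0 contour** (`f0_contour()`): autocorrelation pitch tracking on 40 ms
Hann-windowed frames, 10 ms hop, FFT-based autocorrelation, search range
60–400 Hz. A frame is voiced when its normalized autocorrelation peak is at
least 0.45 *and* its energy is within 35 dB of the loudest frame (the energy
gate stops background noise from being "pitched"). The peak lag is refined
by parabolic interpolation and the track is median-smoothed (width 5) to
remove isolated octave errors. **F0STD** is the sample SD over voiced frames.

**Intensity contour** (`intensity_contour()`): 10 log10 of mean squared
amplitude per 40 ms frame, frames more than 40 dB below the maximum are
excluded as silence. **INTSTD** is the SD over active frames, in dB.

**F1 contour** (`f1_contour()`): linear-prediction analysis (order 12 at
16 kHz, autocorrelation method, 0.97 pre-emphasis, Hamming window) on frames
voiced in the F0 contour; F1 is the lowest prediction-polynomial root between
200 and 1200 Hz with bandwidth below 700 Hz. LPC on strongly harmonic signals
carries a known harmonic-sampling bias of up to a few tens of Hz; the
biomarker is the *variability* (**F1STD**), which is insensitive to that
bias.

**Voice-activity segmentation** (`detect_speech_pauses()`): 30 ms frames,
10 ms hop, classified by level against an adaptive threshold
`max(noise floor + 12 dB, 30th percentile level)` where the noise floor is
the 5th percentile level, capped at 25 dB below the loudest frame (so
recordings with no true pauses do not have their quietest words misread as
pause). Decisions are smoothed morphologically: interior pauses shorter than
`min_pause` (0.15 s) are merged into speech, then speech islands shorter
than `min_speech` (0.10 s) are merged into pause. The result tiles
`[0, duration]` exactly. From it, `pause_features()` computes **SPTIME**
(net speech time), **SILTIME** (total pause time), **SILPERC**
(pause percentage of total), **SILSPRAT** (pause/speech ratio), **SILDUR**
(mean pause duration; 0 when no pause exists), and **SILVAR** (median
absolute deviation of pause durations; 0 below two pauses — a robust spread
measure, since pause distributions are heavy-tailed).

SILPERC and SILSPRAT are strictly increasing functions of one another at
fixed total duration, so every rank-based statistic downstream (H, p, AUROC,
Spearman ρ) is identical for the two. The package keeps both because the
evaluation catalog defines both; the test suite asserts the identity.

## 3. Linguistic and cognitive biomarkers

Transcripts arrive *pre-annotated* as CoNLL-U (tagging, chunking, and forced
alignment are upstream concerns): universal POS tags, lemmas, a
function-word flag (`Func=Yes` in MISC), word time anchors
(`StartTime`/`EndTime`, seconds), and NP/VP/PP phrase spans (BIO chunk tags,
or a sidecar span table when spans overlap).

* **WORDCNT, WORDLEN**: count and mean character length of *content* words
  (function words excluded — closed-class tokens say little about lexical
  access). **SENTCNT, SENTLEN**: sentence count and mean sentence length over
  *all* tokens (sentence length measures the utterance, not its content
  subset).
* **NOUNCNT … AUXCNT**: raw counts per POS class. Counts, not rates:
  shrinking narrative length is part of the phenomenon.
* **NPCNT, VPCNT, PPCNT**: phrase-span counts; missing (with a reason flag)
  when no phrase layer exists for a language.
* **RHYSTD**: sample SD of inter-word-onset intervals. Defined on intervals,
  not raw timestamps (the SD of timestamps grows with recording length);
  translation-invariant, scales under time dilation. Missing with a
  `no-word-alignment` flag when the transcript carries no time anchors.
* **IU**: informational units — the number of checklist items (salient
  picture events, each with one or more acceptable lemmas) mentioned at
  least once. Item-level and type-based: repetition does not inflate it.
  Checklists for the two picture-description tasks ship in
  `inst/extdata/iu_checklist_picture_*.json`.

Degenerate inputs (empty transcript, all function words, no phrases, no
alignment) yield `NA` values with reason flags rather than errors; analysis
proceeds on the remaining biomarkers, mirroring how heterogeneous cohorts
are handled in practice.

## 4. Statistics

* **Kruskal–Wallis** (`kw_test()`): mid-ranks, standard tie correction,
  p from the χ² approximation with k−1 degrees of freedom at all sample
  sizes (the field's convention). An all-tied sample returns H = 0, p = 1.
  For validation, an exact permutation p (full enumeration, two groups) is
  available; the test suite checks it against an independent oracle. The χ²
  p tracks the exact p to within ~0.05 at n = 8 per group (it approximates
  the mid-p convention); both are reported honestly rather than pretending
  tighter agreement.
* **Effect size**: η² = (H − k + 1)/(n − k), floored at 0 — the rank-based
  proportion of variance attributable to groups, adjusted for the k − 1
  expected under the null.
* **AUROC** (`auroc_stat()`): the Mann–Whitney statistic scaled to [0, 1],
  ties counted half, reported orientation-free as max(A, 1 − A); direction
  is carried separately by the **observed behavior** (sign of the PD-minus-CN
  median difference).
* **FDR**: Benjamini–Hochberg within each biomarker *family* (acoustic,
  linguistic, cognitive), separately per dataset and task — the families are
  scientifically distinct hypothesis sets with very different sizes, and
  pooling them would let the large acoustic family dominate the correction
  applied to the two cognitive biomarkers.
* **Severity correlations** (`correlate_severity()`): Spearman ρ between
  biomarker and each available clinical scale, PD subjects only (controls
  have no severity), values standardized first (a strictly monotone map, so
  ρ is unchanged — kept for parity with reporting conventions and asserted
  as an invariance test), BH within family pooled over scales.

## 5. Robustness adjudication

`adjudicate_robustness()` deems a biomarker robust when, within some task
class for which it has an expected direction, all of:

1. significant (FDR-adjusted) results in at least **two distinct datasets**;
2. **every** significant result's observed behavior equals the expected
   direction for that task class;
3. **every** significant severity correlation has the sign implied by the
   expected direction (vacuously true when none is significant).

Conditions are evaluated **per task class** because two biomarkers carry
opposite expectations by design: net speech time and rhythm variability fall
in spontaneous speech (shorter, more static narratives) but rise in reading
(slower, more irregular reading). A biomarker passing in one class is robust
even if another class shows a protocol-driven reversal — task robustness and
cross-language robustness are distinct questions, and conflating them would
wrongly unseat biomarkers whose "inconsistency" is an expected property of
the elicitation, not noise.

The expected-direction catalog, the significant test results, and the
significant severity correlations of a published six-cohort multilingual
study ship as CSV fixtures; applying the rule to them reproduces the
published 13 robust biomarkers and per-dataset significance tallies exactly
(asserted in the acceptance tests). A few cells whose printed typography
conflicted with the source's running text are encoded per the running text
and annotated in the fixtures' `note` column.

## 6. The synthetic cohort generator

Real clinical recordings are restricted, so validation rests on synthesis
with known ground truth.

**Subject model.** A speaker is a draw from `base_subject_params()`:
pitch mean 140 ± 15 Hz and pitch SD 25 ± 8 Hz; intensity SD 4 ± 1.2 dB;
F1 center 500 ± 30 Hz, F1 spread 60 ± 15 Hz; a pause process with Poisson
rate 0.35 ± 0.08 s⁻¹ and lognormal durations (location log 0.5 ± 0.25,
shape 0.35 ± 0.10); net speech target 20 ± 4 s; speaking rate
2.5 ± 0.4 words/s with onset jitter 0.08 ± 0.025 s; and a lexical profile
(POS class weights, word/sentence lengths, phrase rates per sentence,
checklist coverage 0.70 ± 0.12). All values are clamped to physical bounds.

**Effect planting.** An `effect_plan()` row (biomarker, task class,
direction, magnitude, severity link) shifts the PD mean of the biomarker's
generative parameter by `magnitude` between-subject SDs. When several
biomarkers map to one parameter (the pause rate drives SILTIME, SILPERC and
SILSPRAT alike; narrative length drives SPTIME, WORDCNT and SENTCNT) the
largest magnitude wins rather than stacking. Severity coupling uses a
Gaussian copula with coefficient `2 sin(π ρ_s / 6)`, the classical
conversion giving a target *Spearman* correlation `ρ_s` between parameter
and the latent severity; clinical scores (a motor total 25 ± 10 clamped to
[3, 80], its speech item, and an ordinal 1–5 stage in half steps) are
monotone transforms of that latent severity, so the rank link carries over
(up to rounding ties).

**Audio.** Speech is an alternating sequence of words and pauses: each word
is a pulse train of the first eight harmonics (1/k roll-off) of an AR(1) F0
trajectory (φ = 0.98 on a 10 ms grid, stationary SD equal to the subject's
pitch SD), filtered by a per-word second-order resonator (center from the
subject's F1 distribution, 80 Hz bandwidth), with per-word dB amplitudes of
the subject's intensity SD, 5 ms raised-cosine edges, a −60 dBFS noise
floor, and 0.25 s lead-in/out silences. Pauses are floored at 0.25 s so they
sit above the VAD's `min_pause`. This is deliberately *not* a naturalistic
vocoder: it is the simplest signal family for which every extractor has
recoverable ground truth — harmonic (pitch is defined), resonant (F1 is
defined), amplitude-modulated (intensity variability is defined), and
silence-punctuated (pauses are defined).

**Transcript.** POS tags are drawn from the subject's lexical profile plus a
fixed closed-class allocation; lemmas are synthetic types (checklist lemmas
are planted into content slots with the subject's coverage probability);
sentences are segmented at the subject's mean length; NP/VP/PP spans are
Poisson per sentence. Token time anchors equal the true word onsets/ends, as
a forced aligner would provide.

**Determinism.** All randomness flows from one master seed through
deterministic per-subject streams (`seed` and a subject counter combine via
fixed multipliers modulo 2³¹ − 1), so any subject's recording can be
regenerated independently and manifests are exactly reproducible.

**Two speeds.** `generate_cohort(materialize = "full")` writes WAV and
CoNLL-U files; `simulate_biomarker_table()` is a parametric fast path that
draws biomarker values directly from plausible population levels with the
planted shifts and severity links applied at the biomarker level (deriving
SILPERC/SILSPRAT from the simulated times to preserve their rank identity).
Monte-Carlo studies that need hundreds of replicates (type-I error of the
family-wise FDR pipeline, plant-and-recover adjudication over many seeds)
use the fast path; fidelity of the audio chain itself is established
separately by parameter-recovery tests on full synthesis (100 subjects per
parameter, Spearman ρ ≥ 0.8 between planted and extracted values). In the
rhythm-jitter recovery experiment the competing pause process is disabled,
because inter-onset intervals are correctly dominated by pauses when pauses
are present — a property of the biomarker, not an extractor defect.

## 7. Problem sizes and limitations

The pipeline targets cohort-scale problems: tens to a few hundred subjects
per dataset, recordings of seconds to a few minutes, biomarker tables of
thousands of rows. Extraction is the only expensive stage (a 20 s recording
takes on the order of a second); statistics and adjudication are effectively
instantaneous at these sizes.

Known limitations, all deliberate:

* The loudness normalization is a single-gate approximation, not a
  standards-compliant meter; only INTSTD depends on it.
* The pitch tracker assumes one voice, 60–400 Hz, and clean recordings; no
  octave-cost dynamic programming is used beyond median smoothing.
* The F1 estimator reports the lowest admissible LPC root; on dense harmonic
  spectra its absolute value is biased, though its variability is stable.
* The VAD is energy-only; breath noise or loud background events will read
  as speech.
* The generator's speech is schematic (harmonic pulse words, silence
  pauses); it validates extractors and statistics, not perceptual realism.
* Expected directions must be configured for every biomarker × task class
  that is tested; the adjudicator refuses to guess and errors on gaps.
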