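---
title: "Frequency-tagged EEG measures of auditory statistical learning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-tagged EEG measures of auditory statistical learning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In the artificial-language paradigm for auditory statistical learning (SL),
listeners hear a continuous stream of consonant–vowel syllables at a fixed
4 Hz rate. Hidden in the stream are six tri-syllabic pseudowords: within a
word the transitional probability (TP) between syllables is 1, while between
words it is 0.2. If listeners pick up these statistics, the brain's response
should contain not only a 4 Hz syllable-rate component but also a component
at the word rate, 4/3 ≈ 1.333 Hz, and its harmonics — frequencies that are
"tagged" by design. Inter-trial phase coherence (ITPC) of the EEG at those
frequencies is the neural measure of learning.

The catch is acoustic: syllables differ in their amplitude envelopes, and
because each syllable occupies a fixed position within its word, the
stimulus itself has energy at the word rate. A word-rate peak in the EEG
therefore conflates acoustics with learning. The remedy implemented here is
a *position-controlled baseline*: streams built from the same 18 syllables,
with every syllable kept at its original within-triplet position, but with
uniformly low TP. Acoustically the baseline matches the language stream at
the word-rate frequencies; any ITPC difference between conditions is then
attributable to learning.

`freqtagsl` implements this entire design as testable code: stimulus
generation, a synthetic EEG and behavior generator with known ground truth,
and the full analysis chain (ITPC, group and individual permutation
statistics, Bayes factors, mixed-model block regression, behavioral
scoring, and neural–behavioral correspondence).

## Stimulus model

**Streams.** Syllables last exactly 250 ms; triplets therefore occupy
750 ms. Language streams schedule the six pseudowords in shuffled blocks of
six, which keeps word counts balanced within ±1, spreads words evenly over
time, and forbids immediate repetition; the between-word TP is 0.2 by
symmetry (five equiprobable successors). The baseline generator draws each
transition uniformly from exactly 5 of the 6 position-legal successors
(variant `tp02`, TP 0.2): within a triplet it excludes the successor that
would recreate the original word bigram, across a triplet boundary it
excludes the previous triplet's initial syllable (which also forbids
repeats). A second variant, `all_combinations`, allows all 6 successors
(TP 1/6). Both variants are provided because "all combinations allowed"
and "TP = 0.2" describe different processes; `tp02` is the default since it
realizes the commonly stated 0.2 and keeps word bigrams out of the baseline.
Note one subtlety: the boundary exclusion depends on the previous triplet,
so the *first-order marginal* TP from a word-final syllable to initial
syllables converges to ≈1/6 even though each available successor has
probability 0.2 at every step. `transition_matrix(mode = "design")` reports
the conditional-on-available value (0.2) and flags the context dependence.

**Streams are 256 triplets (192 s ≈ 3.2 min), three per condition**, with
5 s linear onset/offset amplitude ramps — the paradigm's usual ~3.2-minute
exposure blocks, with 256 the closest integer triplet count.

**Envelopes.** Since natural recordings are not part of the package, each
syllable has a gamma-shaped attack–decay envelope kernel
$A\,(t/t_a)^{t_a/t_d}\,e^{-(t-t_a)/t_d}$ with per-syllable attack
$t_a \in [20, 70]$ ms, decay $t_d \in [40, 150]$ ms and peak amplitude
$A \in [0.85, 1.15]$, from a fixed packaged table. A single *kernel
heterogeneity* scalar interpolates between this table and the flat mean
kernel; at 0 the stimulus is acoustically flat and all word-rate acoustic
peaks vanish — the control used throughout the tests. The modulation
spectrum is a Welch average (15 s Hann segments, 50% overlap, per-segment
DC removal, power normalised to unit sum over 0–10 Hz); 15 s segments put
1.333, 2.667, 4 and 5.333 Hz on exact bins. With the default kernel table
the 4 Hz syllable peak dominates and modest local peaks appear at 2.667 and
5.333 Hz; the 1.333 Hz fundamental itself is small — deliberately so, as
the word set mimics a lexicon *screened to minimise* word-rate acoustic
peaks (`screen_lexicon_candidates()` reproduces that screening).

## Synthetic EEG

`simulate_eeg()` builds each recording as

* a syllable-rate component: syllable-onset impulses weighted by each
  syllable's envelope amplitude, convolved with an 80 ms single-cycle
  damped sinusoid, scaled by the subject's `syllable_gain`, with a
  mid-frontal Gaussian topography;
* a word-rate component: triplet-onset impulses convolved with a 300 ms
  biphasic kernel, scaled by `kappa + lambda` in the language condition and
  `kappa` in the baseline, with a mid-central topography;
* 1/f Gaussian noise of scale `noise_sigma` (exponent 1), independent per
  channel plus a shared global component (variance fraction 0.3) to induce
  realistic inter-channel correlation.

`kappa` is the *acoustic* word-rate gain — present in both conditions, it is
the confound the baseline condition exists to cancel. `lambda` is the
*learning* gain, present only in the language condition; it is the latent
ground truth all recovery tests refer to. The montage is a synthetic
64-channel concentric-ring layout (labels `A1..B32`), not digitized 10–20
coordinates; topographies and the cluster adjacency (distance < 0.35 of the
head radius) live on it.

Two features of real data are deliberately *not* emulated. First, the model
is additive, so it has no mechanism for the empirically observed *reduction*
of 4 Hz ITPC during language listening; in fact the word kernel's third
harmonic adds a little 4 Hz energy in the language condition, so the
one-tailed syllable-rate test (whose a priori direction is negative) should
be non-significant on simulated data — passing tests say nothing about that
real-data phenomenon. Second, there are no artifacts (blinks, drifts,
ECG): preprocessing of real recordings is out of scope, and simulated data
enter the spectral analysis clean.

## Cohort and behavior

`sample_cohort()` draws, per subject: learner status (fraction 0.7 of the
cohort), `lambda ~ N(1, 0.35)` truncated at 0 for learners (0 otherwise),
`kappa ~ N(0.6, 0.15)` truncated at 0, `syllable_gain ~ N(1, 0.1)`, and
`noise_sigma ~ N(13.5, 1)`. Behavioral effects couple to the same `lambda`:
2AFC accuracy `p2afc = 0.5 + 0.05 * lambda` (clipped to [0.5, 0.95]), a
reaction-time advantage `rt_effect = 0.2 s * lambda` and a hit-rate
advantage `hit_effect = 0.25 * lambda` for targets in the final position of
learned words.

Two of these constants deserve comment. The 2AFC link uses 0.05 per unit
`lambda` so that a typical learner sits near 55% — the explicit task's
near-chance regime (group means ~53%, very few subjects above the 65%
chance cutoff); a steeper link would make the explicit task the *most*
sensitive measure, inverting the phenomenon of interest. `noise_sigma` was
calibrated once, by Monte-Carlo sweeps at the default effect sizes, to the
low-individual-prevalence regime: the group-level word-rate effect remains
present with modest t values while only a minority-to-half of subjects
reach individual-level neural significance — always fewer than the
implicit behavioral task detects. The realised fraction varies
considerably between simulated cohorts (the learner draw and the
per-subject `lambda` draws dominate it), so it is a regime, not a fixed
percentage. These are the generator's study conditions; they are not
adjusted per analysis.

The implicit task builds 24 trials (4 per word-final target syllable) of 45
syllables at 2 Hz (22.5 s), with 4–8 targets per trial in the categories
`pseudoword_3rd`, `nonword_1st`, `nonword_3rd`. Target-bearing triplets
occupy non-adjacent slots so the 1 s response windows never overlap. A
press within (0, 1] s of a target is a hit (first press only); everything
else is a false alarm. Hit RTs are log-normal (dispersion 0.25) with the
median shifted by `rt_effect`, floored at 150 ms and truncated to the
scoreable window; false alarms arrive as a 0.02 Hz Poisson process outside
windows.

## Analysis chain

**Epoching.** 4.5 s epochs (6 triplets), consecutive and non-overlapping,
each starting exactly at a triplet onset, anchored at the first onset at or
after the 5 s ramp. With 256 triplets this yields 41 epochs per block
(249 post-ramp triplets, ⌊249/6⌋). Ramp exclusion is configurable; the
choice maximises epoch independence while honouring exact triplet
alignment.

**ITPC.** Per channel and DFT bin in 0.3–6 Hz: Hann-taper each epoch, take
the DFT, keep only the phase $\phi_k$, and compute
$\mathrm{ITPC} = |\tfrac1N \sum_k e^{i\phi_k}|$. The 4.5 s epoch puts the
four frequencies of interest (1.333, 2.667, 4, 5.333 Hz) on exact bins
(6, 12, 18, 24 of the 1/4.5 Hz grid); no zero-padding or interpolation is
used. A bin with exactly zero amplitude in an epoch has no phase; such
epochs are excluded from that bin with a warning and N adjusted (the
simulator's noise floor makes this a theoretical contingency). ITPC is
computed per condition over all blocks pooled (main analysis) and per block
(regression analysis).

**Group inference.** At each FOI, the electrode-averaged ITPC enters a
one-tailed paired t test — directions fixed a priori: positive
(language > baseline) at the word-related FOIs, negative at 4 Hz — and a
directional default-prior (JZS) Bayes factor: Cauchy prior of scale
$\sqrt2/2$ on the standardised effect, truncated to the tested direction,
integrated by nested quadrature against the exact noncentral-t integral
representation (relative tolerance 1e-8; R's built-in noncentral-t density
is not accurate enough for stable Bayes factors). No correction is applied
across the four FOIs, as the directions and frequencies are fixed a priori.

**Cluster permutation.** Per electrode one-tailed paired t; electrodes with
p < 0.05 are grouped into adjacency-connected clusters; cluster mass is the
summed t; the null is the maximal cluster mass over within-subject
condition sign flips (default 1000), and cluster p uses the add-one rule
(1 + #{null ≥ obs})/(1 + n). Sign flips only change electrode means, not
sums of squares, so all permutation t values come from one matrix product —
this keeps 500-replicate calibration runs cheap.

**Block regression.** `ITPC ~ Condition * Block + (1 | Participant)` by
REML via lme4, Satterthwaite df via lmerTest. Condition is coded +1/-1
(language/baseline); blocks use forward Helmert contrasts whose columns
compare level 1 vs 2 and the mean of 1 & 2 vs 3 — the labelling that
defines the reported coefficients (the alternative reading, each level
against the mean of *subsequent* levels, is the same comparison set in
reverse order; the table labels win). With zero random-intercept variance
the fit coincides with OLS, to which the function falls back on degenerate
(e.g. noiseless) input.

**Individual inference.** Per subject, the observed statistic is the
electrode-averaged ITPC difference at each FOI (sign-adjusted by the a
priori direction). The null swaps a random half of the epochs between
conditions — an equal-sized exchange of ⌊min(N1,N2)/2⌋ epochs each way,
preserving each condition's epoch count because ITPC is N-dependent — and
recomputes the difference (default 1000 times, add-one p). A subject
counts as a neural learner if p ≤ 0.05 at any word-related FOI; the 4 Hz
flag is kept separate. The analysis can be restricted to the electrodes of
significant group-level clusters; `run_experiment()` runs both variants.

**Behavior.** 2AFC sessions are scored against the exact binomial tail and
against a simulated 1000-session guessing null whose interpolated 95th
percentile reproduces the ~65% chance cutoff of a 36-trial test. Detection
effects (ΔHR over all targets; ΔRT over hits only, the hits-only reading of
an ambiguous convention) are tested by category relabeling with original
group sizes. Correspondence analyses correlate the word-FOI-averaged
language-condition ITPC with each behavioral measure and compare behavioral
measures between neural learners and non-learners with Welch's
unequal-variance t test.

## Numerical choices and degenerate inputs

* All randomness flows from named integer seeds; every stage derives child
  seeds via `child_seeds()`, so any stage can be reproduced in isolation.
* Permutation p values always use the add-one correction, so p = 0 is
  impossible.
* Zero-variance paired differences are an error (the t statistic is
  undefined), not a silently infinite t.
* Zero-variance electrodes in the cluster test carry t = 0 rather than NaN.
* Candidate-screening ties break by input order; all tie-breaks are
  deterministic.
* Times are in seconds, sample indices 0-based at the file-format boundary,
  epoch windows half-open.

## Problem sizes

Default analyses use the full study scale: 30 subjects, 3 blocks × 2
conditions of 256 triplets at 256 Hz on 64 channels, and 1000-permutation
tests. The test suite exercises the same code paths at reduced scale
(64 Hz sampling, shorter streams, 150–500 permutations) and at full scale
once in the acceptance tests; calibration checks use 400–500 Monte-Carlo
replicates, at which a true rate of 0.05 is estimated with a standard error
of ~0.011.

## Limitations

* The montage and envelope kernels are synthetic stand-ins; topographic
  claims only have meaning relative to the simulated maps.
* The generator cannot produce the real-data 4 Hz suppression effect (see
  above), nor artifacts, volume conduction, or coarticulation.
* The behavioral link is linear in `lambda` with a single latent factor;
  real explicit/implicit measures dissociate more than this model allows.
* Group-level real-data statistics are reproduced only qualitatively via
  simulation; the printed Bayes factors are recomputed exactly from their
  test statistics, which is an arithmetic check, not a data replication.
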