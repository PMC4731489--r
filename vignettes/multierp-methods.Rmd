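---
title: "Methods: simulating and analysing a gamified multi-ERP oddball session"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a gamified multi-ERP oddball session}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multierp)
```

## The paradigm

`multierp` implements a computable version of a gamified audiovisual oddball
task designed to elicit ten event-related potentials (ERPs) in one session:
C1, P50, MMN, N1, N170, P2, N2pc, LRP, P300 and ERN. The task runs in three
game levels of increasing complexity:

* **Learn** — passive fixation on odd-numbered blocks, side-report button
  presses on even blocks;
* **Who** — responses in every block; in half of the blocks
  (pseudo-randomly allocated) each button press immediately triggers a tone
  (`cd_immediate`), in the other half the tone arrives after a random delay
  or at the response timeout (`cd_random`), which sets up the
  corollary-discharge (self- versus externally-triggered) N1–P2 contrast;
* **Discern** — a meaningful/ambiguous discrimination (intact face or
  Kanizsa figure versus their distorted versions) whose button mapping
  reverses halfway through the level.

Each level holds 448 trials in 16 blocks (25 stimulus + 3 fixation-only
baseline trials per block). Within a block one of four two-tone image types
is *frequent* (80% of stimulus trials, always on one side of fixation) and
two other types are *rare* (20% total, on the opposite side). A trial is
60 ms pre-stimulus mask + 240 ms stimulus + 700 ms response window +
200 ms end baseline, extended by a uniform 0–700 ms jitter: durations are
1200–1900 ms with mean 1550 ms. Paired 15 ms tones (standard 1000 Hz,
deviant 1500 Hz; the second tone 500 ms after the first) begin at −240,
−40 or +160 ms relative to visual onset, and small checkerboards appear at
the top or bottom of the display as visual distractors (driving the C1
polarity flip).

## Design decisions in the schedule generator

Several stated design constraints interact, and a handful of points are
unstated; the generator resolves them as follows.

**Tone percentages are fractions of tone slots.** The stated tone rates
(standards "80% of trials", deviants "10%") cannot apply to all trials:
every paired-tone trial must be followed by three toneless trials, capping
tone-bearing trials at 25%. We therefore treat the percentages as the
composition of dedicated *tone slots*: 80% standard–standard pairs, 10%
pairs with a deviant second tone, 10% silent slots. Slots fall on every
4th stimulus trial of a block, five per block (stimulus trials 1, 5, 9,
13, 17), giving 80 slots per level and *exact* integer counts 64/8/8.
Deviants are restricted to the S2 position, so the deviant-vs-standard
(MMN) contrast at S2 is not confounded with the S1/S2 gating (P50)
contrast. What fills the remaining 10% of slots the design leaves
unstated; silent slots are our choice.

**Rare-type split.** 2.5 rare trials of each type per block is impossible;
blocks alternate 3/2 and 2/3, making each rare slot total exactly 40 of
the 400 stimulus trials (10%) per level.

**Rare placement.** Rare positions are uniform among stimulus trials 3–25;
the first two trials of each block are always frequent (standard oddball
practice; the reference design is silent here).

**Feedback bands.** The stated message bands are "below 85%", "85–95%"
and "greater than 95%"; both edges are inclusive in the middle band, making
the feedback a total monotone step function on [0, 100].

**Jitter and delays.** The end-baseline jitter is discrete uniform on
0–700 ms at 1 ms resolution (only "randomly extended" is stated). The
`cd_random` tone delay is uniform on 100–500 ms after stimulus offset,
with the tone at the 700 ms timeout when no response occurs (no
distribution is stated).

**Markers.** Every trial carries a pipe-separated condition code (level,
block, mode, image, side, category, tone condition, distractor, button,
accuracy), bijective with its condition tuple; a full three-level run
realises over 500 distinct codes. Numeric aliases are a sorted sequential
registry persisted with the schedule — no hashing, so codes are portable.

## Stimuli

The original degraded-photograph (Mooney) face set is not redistributable,
so the stimulus bank generates *synthetic stand-ins*: smoothed Gaussian
random fields thresholded at the median into two-tone images, bilaterally
symmetrised with two dark upper-half blob features. Their "distorted"
versions are block-scrambled permutations of the same image (the original
distortion method is not described), which exactly preserves the pixel
histogram and hence mean luminance. Kanizsa triangles are three notched
discs facing the centroid; distorted variants rotate the notches outward
by seeded random angles, keeping total ink identical within rasterisation
error (<1%). Mean-luminance equalisation flips randomly chosen pixels of
the over-represented tone until every image is within tolerance of the
set's grand mean — the mean-luminance part of histogram-matching
toolchains, which is all the block-level luminance claim requires.

## The EEG simulator

The simulator renders a 19-channel, 250 Hz recording as

\[ X = N_{1/f} + \sum_k T_k \]

where \(N_{1/f}\) is spectrally-synthesised pink noise (log–log spectral
slope ≈ −1) and each template \(T_k\) adds a Gaussian-envelope deflection
time-locked to its events, scaled by a condition rule and a topography.
The defaults (see `default_templates()`) put each component inside its
conventional latency window with condition effects in the conventional
directions: rare P300 +5 µV versus frequent +1 µV at Pz (peak 400 ms);
ERN −4 µV incorrect versus −1 µV correct at FCz (+60 ms post-response);
C1 ±1 µV flipping with distractor position at POz; N170 stronger for
shapes than faces and scaled 0.7/0.85/1.0 across Learn/Who/Discern;
N1/P2 attenuated ×0.5 when the corollary-discharge tone is
self-triggered; P50 S1 +2 µV versus S2 +1 µV (gating ratio 0.5, measured
as the S2/S1 amplitude ratio); MMN −3 µV deviant versus −0.5 µV standard;
N2pc −1.5 µV contralateral to the salient image; LRP −2 µV contralateral
to the responding hand. These amplitudes are *configuration*, not claims
about any human data: they are the ground truth the recovery tests check
against.

**Zero-sum topographies.** All template topographies sum to zero over the
montage (dipolar fields, with return weights over channels no contrast
measures). Real average-referenced scalp fields are zero-mean; more
practically, a non-zero-sum topography would reappear (scaled by its mean
weight) at *every* channel after average re-referencing, mixing, e.g.,
the large N170 into the small P50 measured fronto-centrally. The early
development history of this package includes exactly that failure mode.

**Behaviour.** Reaction times are log-normal (median 420 ms, log-sd 0.25)
truncated by the 700 ms response window (slower draws are misses ≈ 2%);
accuracy is 0.97/0.95/0.85 for Learn/Who/Discern with an extra 0.25 lapse
probability in the first post-reversal Discern block. This realises the
stated qualitative behaviour — near-ceiling performance in the first two
levels, more errors and reversal lapses in the third — and produces
enough incorrect responses (~60 per Discern run) for a response-locked
ERN average.

**Noise level.** The default background is 2 µV RMS per channel in the
0.1–40 Hz band. This is quieter than raw scalp EEG, deliberately: the
default SNR is *defined* by the recovery property the package promises —
a condition cell of ~40–50 epochs must recover its injected window-mean
amplitude within 20%. For 1/f noise the per-epoch window-mean standard
deviation after baseline correction is ≈ 1.1 × RMS (low frequencies
barely average out within a 100 ms window), so the scarcest cell (48
deviant tones against a 2 µV injected MMN difference) needs RMS ≈ 2 µV
for a ~2.5-sigma margin; an early 5 µV choice based on white-noise
intuition failed exactly this power analysis. One simulated "subject"
also has no trial-to-trial amplitude/latency variability or artifacts,
so a quiet background is the honest analogue of a clean averaged
session. Users exploring robustness should raise `noise_uV`; the default
is the dial that makes a green recovery test mean "the chain is
unbiased", not "the chain is robust to arbitrarily poor data".

**What the simulator does not emulate** — and hence what a green recovery
test does not establish: volume conduction and realistic topographic
mixing, ocular/muscle artifacts (off by default), latency and amplitude
variability across trials, between-subject variability, non-stationary
background rhythms, and electrode-level noise correlations. Green tests
establish that the *analysis chain* is correct and unbiased for
linearly-superposed, time-locked components in 1/f noise — not that it
would be robust to everything real data does.

## Preprocessing

The chain mirrors a standard acquisition-and-cleaning pipeline at desk scale: 0.1 Hz first-order
Butterworth high-pass and 40 Hz Hamming windowed-sinc FIR low-pass, both
applied zero-phase (forward–backward IIR; symmetric FIR). The acquisition
system's causal first-order filter would shift ERP latencies; zero-phase
application is the deliberate divergence, noted here. Peri-stimulus
epochs are −1 to 2 s (response-locked −0.5 to 0.8 s, our choice; no
convention pins it); baseline windows are −200–0 ms stimulus-locked,
−450 to −250 ms response-locked and −100–0 ms tone-locked. Average
re-referencing is applied at the recording level. Subspace-reconstruction
artifact cleaning and ICA are *replaced* by absolute-threshold epoch
rejection (100 µV default): the simulator's artifacts are amplitude
excursions, for which a threshold is sufficient and dependency-free. An
ICA-specific short epoch window (−0.5 to 0.8 s) is not implemented.

## ERP contrasts

`builtin_contrasts()` registers the ten analyses: C1 (top-vs-bottom
distractor, POz, 40–120 ms), P50 (S1-vs-S2 paired tone, 30–80 ms), MMN
(deviant-vs-standard S2, 150–250 ms), N1 and P2 (externally- versus
self-triggered corollary-discharge tone at Cz, 70–130 / 160–240 ms), N170
(four-level image factor at PO8, 170–250 ms), N2pc
(contralateral-minus-ipsilateral, PO7/PO8, 200–300 ms), LRP (double
subtraction \(((C3-C4)_{right} + (C4-C3)_{left})/2\), response-locked,
−150–50 ms), P300 (rare-vs-frequent at Pz, 300–500 ms) and ERN
(incorrect-vs-correct at FCz, 0–100 ms post-response). All windows are
configuration and overridable. The N170 condition mapping is FacePresent =
intact face stand-in, FaceAbsent = distorted face, ShapePresent = Kanizsa,
ShapeAbsent = distorted Kanizsa.

Because image type correlates with presentation side within a block (the
frequent image stays on one side), the N170 factor averages are computed
*side-balanced* — the unweighted mean of the per-side condition means —
so the lateralised N2pc cannot masquerade as an image-factor effect.

## Statistics

Pointwise permutation tests follow the paradigm's standard recipe: paired *t*
(sign-flip permutation, exact under symmetry) for two-condition
contrasts, one-way repeated-measures ANOVA (condition labels permuted
within unit) for the four-level image factor, 2000 permutations, p < 0.05
with Benjamini–Hochberg FDR over the full time (or time–frequency) grid.
With 2000 permutations the smallest attainable p is 1/2001. A single
simulated run has no between-subject dimension, so the paired units are
interleaved sub-averages of epochs within condition (12 by default) — the
standard split-half/jackknife-style device, documented in every report
the CLI writes. For k = 2 the ANOVA route raises an error directing users
to the paired test (a two-level "repeated-measures ANOVA" is the paired
*t* in disguise; we keep one canonical route rather than two).

ERSP uses 5-cycle Morlet wavelets on a 3–40 Hz log-spaced grid
(30 points), power averaged over epochs and expressed as
\(10\log_{10}(P/\bar P_{baseline})\); ITC is the resultant length of unit
phase vectors, in [0, 1] by construction. Wavelet cycle count and grid are
EEGLAB-style defaults. Power spectra are
Hann-windowed Welch averages with one-sided density scaling (Parseval
consistent).

## The recovery experiment

`recovery_experiment()` is the package's end-to-end property check: it
simulates complete three-level runs, pushes them through the full chain,
and compares every contrast's window-mean amplitude against a
*closed-form* expectation — injected amplitude difference × channel
weight × window mean of the Gaussian envelope, summing over all templates
locked to the same events. The N1 and P2 of the corollary-discharge
complex overlap each other, so both cross terms appear in each other's
expectation; this is an analytic property of the injected waveforms, not
a fit to the data.

Contrasts are evaluated where the condition-average figures place them
(Who for C1, N1/P2, N2pc, LRP, P300; Discern for N170 and ERN) with one
deliberate exception: P50 and MMN are collapsed over Learn and Discern
only. In Who, every trial carries a response-triggered or random-delay
tone whose N1/P2 land — RT-jittered but with structured lags — inside the
paired-tone epochs at the same fronto-central channels, biasing the
noiseless P50 estimate well outside the recovery band during
development. Excluding the level with the structural
confound is an analysis-design decision made from the noiseless
diagnostic, not a tolerance adjustment. Three full runs are simulated for
the visual/response contrasts; the paired-tone contrasts pool twelve
Learn+Discern runs, because deviant tones are rare by design (8 per
level) and the deviant cell's standard error, not any bias, is what
limits MMN recovery — 192 deviant epochs put it well inside the 20%
band.

## Numerical and degenerate-input choices

Filtering demeans before the high-pass, so constant inputs map to ~0
exactly; FIR application uses reflection padding and FFT convolution with
the symmetric-filter alignment (no phase shift). Epochs whose window
leaves the recording are dropped and counted, never clipped. Threshold
rejection errors out if it would reject everything. `itc()` on a single
epoch warns and returns the degenerate all-ones map. Sign conventions:
negative values plot downward nowhere — stored values are plain
microvolts, negative components (N170, ERN, MMN, N2pc, LRP, C1-top) are
negative numbers. Peak amplitude is the signed extremum (largest
magnitude) within the window. All randomness flows through explicit
seeds; generation, simulation and analysis are bit-reproducible given
`(config, seed)`.

## Known limitations

* Only mean-luminance equalisation is implemented, not full
  histogram/spectrum matching of the stimuli.
* The N170 effect-size sign in reference summary tables is ambiguous (a
  positive mean is quoted for a negative-going component); `cohens_d_vs_baseline()`
  returns the signed d and comparisons of magnitude use `abs()`, leaving
  the ambiguity visible rather than resolving it.
* Source-space analyses (dipole clustering, measure projection) and
  hardware/acquisition concerns are out of scope.
* The EDF export mentioned alongside the flat-binary recording container
  is not implemented; the float32 + JSON sidecar + TSV events trio is the
  interchange format.
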