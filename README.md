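# multierp

Simulation and analysis of a **gamified multi-ERP oddball paradigm** — a
single EEG session designed to elicit ten event-related potentials at once:
C1, P50, MMN, N1, N170, P2, N2pc, LRP, P300 and ERN.

The package is aimed at EEG methodologists and paradigm designers who want
a fully computable version of such a session: a seeded generator of the
complete three-level trial/block/event schedule (with structured condition
markers), programmatic two-tone stimuli, a synthetic EEG simulator with
known injected ground truth, and the standard ERP analysis chain — so that
every step from design decision to FDR-masked contrast can be tested.

## The paradigm in one paragraph

Three game levels of increasing complexity (passive/active observation →
agency detection with corollary-discharge tones → meaningful/ambiguous
discrimination with a mid-level rule reversal), each 448 trials in 16
blocks of 25 stimulus + 3 baseline trials. Every block is a fresh visual
oddball: one of four two-tone image types (Mooney-style face, Kanizsa
triangle, and their distorted versions) is frequent (80%) on one side of
fixation, two others rare (20%, 10% each) on the opposite side. Paired
tones (standard 1000 Hz / deviant 1500 Hz, S2 500 ms after S1) ride on
every fourth stimulus trial at −240/−40/+160 ms relative to visual onset;
top/bottom checkerboard distractors drive the C1. Trials last
1200–1900 ms (mean 1550 ms). Analysis: 0.1–40 Hz zero-phase filtering,
epoching (−1..2 s), average reference, baseline correction, threshold
rejection, condition-average contrasts, ERSP/ITC, and pointwise
permutation tests (paired *t*, or repeated-measures one-way ANOVA for the
four-level image factor; 2000 permutations) with Benjamini–Hochberg FDR.

Core derived statistics, in the field's standard notation:

- LRP(t) = [ (C3 − C4)<sub>right hand</sub> + (C4 − C3)<sub>left hand</sub> ] / 2
- N2pc(t) = mean of contralateral − ipsilateral at PO7/PO8
- ERSP(f,t) = 10·log₁₀( P(f,t) / mean P(f, baseline) ) from 5-cycle Morlet wavelets
- ITC(f,t) = | mean over epochs of e^{iφ(f,t)} | ∈ [0, 1]
- Cohen's d (vs baseline) = mean / SD of baseline-corrected amplitudes

## Worked example

```r
library(multierp)

sch <- generate_level("Who", seed = 42)
sch
#> <erp_schedule> level Who, seed 42: 448 trials in 16 blocks
#>   frequent 80.0% / rare 20.0% of stimulus trials; deviant tones 10.0% of tone slots
#>   trial duration 1200-1899 ms (mean 1542.7)

rec <- simulate_recording(sch, seed = 43)     # 19 ch x 250 Hz, ~11.6 min
rec <- average_reference(filter_band(rec))    # 0.1-40 Hz zero-phase

ev <- rec$events[rec$events$event_type == "stimulus", ]
ep <- baseline_correct(epoch(rec, ev, channels = "Pz"), c(-200, 0))
rare <- average_erp(ep, function(l) l$category == "rare", "Pz")
freq <- average_erp(ep, function(l) l$category == "frequent", "Pz")
round(c(rare = amplitude_measure(rare, c(300, 500), "peak"),
        freq = amplitude_measure(freq, c(300, 500), "peak")), 2)
#> rare freq
#> 5.12 1.18
```

The rare-stimulus P300 peak at Pz recovers the injected +5 µV (frequent
+1 µV) from the 1/f background — the oddball effect the paradigm is built
around. `cmd_analyze(rec, "all", out_dir)` runs all ten registered
contrasts and writes waveforms, permutation p-values, FDR masks, effect
sizes and a markdown report; `recovery_experiment()` is the end-to-end
check comparing every contrast against its closed-form injected
expectation.

There is also a command-line surface:

```sh
Rscript -e 'multierp::main_cli()' generate --level Who --seed 42 --out /tmp/who
Rscript -e 'multierp::main_cli()' simulate --events /tmp/who_events.tsv --seed 43 --out /tmp/who_rec
Rscript -e 'multierp::main_cli()' analyze --recording /tmp/who_rec --erps P300,ERN --out /tmp/results
```

## Layout

- `R/config.R`, `R/schedule.R` — paradigm configuration and the seeded
  three-level schedule generator (markers, feedback, validation)
- `R/stimuli.R` — checkerboards, Kanizsa variants, synthetic two-tone
  face stand-ins, mean-luminance equalisation
- `R/simulate.R` — montage, ERP component templates, behavioural model,
  pink noise, recording composition
- `R/preprocess.R` — filtering, epoching, baseline, average reference,
  threshold rejection
- `R/erp.R`, `R/recovery.R` — the ten-contrast registry, LRP/N2pc
  derivations, amplitude measures, Cohen's d, recovery experiment
- `R/spectral.R` — ERSP, ITC, Welch spectra, permutation tests, BH-FDR
- `R/io.R`, `R/cli.R` — events TSV, flat-binary recordings with JSON
  sidecars, manifests, CLI entry points

See `vignettes/multierp-methods.Rmd` for the full methods account:
model assumptions, parameter choices with units and defaults, what the
simulator does and does not emulate, and known limitations.
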