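---
title: "Quantifying the emergence of embryonic movement from intensity traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the emergence of embryonic movement from intensity traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryomotion)
```

## The measurement model

Late *Drosophila* embryogenesis shows two behavioural phases: a disorganised,
muscle-driven ("myogenic") phase starting around 16 hours after egg laying
(hAEL), and a neurally driven ("neurogenic") phase of rhythmic activity
bouts from roughly 18 hAEL until hatching. Under lateral incident light,
any embryo movement changes the light reflected into the camera, so the
mean grey value (MGV) of a rectangular ROI placed over an embryo is a
sensitive single-channel readout of movement. The package turns per-frame
MGV series into movement quantities in five steps:

1. **Baseline.** A centred rolling average over `baseline_window = 60`
   samples (15 s at the 4 Hz recording rate) tracks the slow background:
   gradual morphological change, and the sigmoidal MGV shift at tracheal
   gas-filling. 15 s sits between the duration of single movements
   (~1 s) and the slowest developmental changes, so subtracting it removes
   the background while leaving movement transients intact.
2. **Rectification.** Movement deflects MGV in either direction, so the
   movement signal is `|MGV - baseline|`.
3. **Noise threshold.** Rectified deviations below
   `noise_threshold = 0.01` MGV units are set to exactly zero. The
   threshold is applied per sample, before any summation, bout detection or
   FFT; this is the simplest reading of a single scalar noise floor and
   makes the "values below threshold are exactly 0" invariant checkable on
   every `movement_trace`. A `threshold_mode = "post_sum"` escape hatch
   exists for sensitivity analysis only.
4. **Hatch crop.** Traces are cut at the annotated hatching time; hatching
   produces a large MGV discontinuity and everything after it is larval,
   not embryonic, behaviour. Hatch times are user annotations;
   `suggest_hatch()` offers an advisory candidate (largest sustained raw
   step in the final third of the record) but is never applied
   automatically.
5. **Phase quantification.** Movement per phase is the sum of thresholded
   rectified deviations over fixed half-open windows: myogenic
   `[16, 18)` hAEL, neurogenic `[18, hatch)`. The boundaries are fixed
   times because the phase transition is defined developmentally, not
   algorithmically; annotated overrides are supported, change-point
   detection is out of scope.

## Spectral analysis and bouts

`sliding_fft()` cuts the movement trace into 1-hr windows advanced in
30-min steps (trailing partial window dropped), subtracts each window's
mean, and reports one-sided amplitudes `2|X_k|/N` with the DC bin removed.
Under the default rectangular taper an on-bin sinusoid of amplitude A reads
exactly A, which pins the normalisation; a Hann taper (amplitude-corrected)
is available for leakage-sensitive work. Window-mean subtraction and DC
removal keep residual slow drift out of the movement band. Because the
original analysis software's amplitude convention is not documented,
amplitudes are comparable only within this pipeline; cohort comparisons use
period shifts, never absolute amplitudes against external colour scales.
The period view re-indexes frequency as p = 1/f inside a default band of
4 s (Nyquist-safe at 4 Hz) to 1800 s (half the FFT window).

Bouts are defined operationally: smooth the thresholded trace with a
centred moving average (10 s), take maximal runs above `bout_threshold`
(0.05 MGV by default — about a fifth of the smoothed within-bout level of
the wild-type preset), merge runs separated by gaps shorter than 10 s, and
drop bouts shorter than 5 s. All four knobs are exposed; the defaults
recover the synthetic generator's ground-truth bouts exactly at zero noise
(the square-wave tests), and `mean_interval` (start-to-start) recovers the
bout period.

## The synthetic generator

`generate_trace()` emulates exactly the structure the analysis assumes:

* a baseline (default level 100) with linear drift
  (`drift_slope`, default 0.2 MGV/h), a logistic tracheal gas-filling step
  (+2 MGV at 19.5 hAEL, 2-min 10–90% rise) and a hatching discontinuity
  (−3 MGV at 21 hAEL);
* a myogenic phase (16–18 hAEL) of Poisson-timed events (3/min) with
  gamma-distributed amplitudes (mean 0.3 MGV, shape 2), each a 1-s
  biphasic (single sine cycle) pulse;
* a neurogenic phase (18 hAEL–hatch) of strictly periodic bouts: 60-s
  rectangular envelopes every 180 s carrying a 1-Hz sinusoid of amplitude
  0.5 MGV (timing jitter defaults to 0 so spectral recovery tests are
  exact);
* additive Gaussian sensor noise, SD 0.003 MGV — mostly below the 0.01
  threshold, as in recordings of unfertilised eggs.

Event pulses and the within-bout oscillation are zero-mean on the sample
grid, so they barely perturb the 15-s rolling baseline and the injected
rectified activity (recorded in the ground truth) is recoverable by the
pipeline. The silenced preset sets `bout_amplitude = 0` and leaves the
myogenic process untouched — the signature of pan-neuronal silencing. The
mutant-like preset halves event and bout amplitudes and shortens the bout
cycle (120-s period, 30-s bouts): less movement in both phases, a higher
bout frequency and shorter bouts. The magnitudes of the mutant effects are
free parameters chosen once to be comfortably detectable at cohort size 12;
the direction of each effect, not its size, is the modelled phenotype.

What the generator does **not** emulate: between-embryo variability of the
preset parameters (cohort scatter comes only from the Poisson event
process, bout jitter when enabled, and sensor noise, so synthetic cohort
p-values are far smaller than real ones), optical physics of reflection,
movement-type structure (head sweeps vs peristalsis), and developmental
timing variability. Passing phenotype tests therefore demonstrates that
the pipeline discriminates the modelled effect directions at realistic
effect sizes — not that it reproduces real biological variance.

`generate_calcium_pair()` builds matched GCaMP-like and tdTomato-like
channels sharing a strictly positive multiplicative motion artifact, with
calcium events as instant-rise transients decaying exponentially
(τ = 6 s; the kinetics are a modelling choice, not a measured constant).
ΔF/F is the channel ratio minus its centred 10-min sliding minimum —
the subtraction form is the default; a division-normalised ΔF/F₀ variant
sits behind `normalise = TRUE`. Negative excursions are retained in sums:
clipping would bias cohort comparisons asymmetrically.

## Numerical choices

* **Centred windows everywhere.** The rolling baseline, bout smoothing and
  ΔF/F minimum all use centred windows (`window %/% 2` samples each side,
  shrinking at the edges). A trailing window would lag the baseline by
  7.5 s and smear movement onsets.
* **Exact reductions.** The rolling mean accumulates by shift-and-add in
  window-index order, so window sums round identically to a naive
  per-window loop; with inputs quantised to dyadic values the equality is
  exact by construction, and the test suite asserts bitwise agreement with
  brute-force oracles on that footing.
* **Baseline leakage.** Movement unavoidably leaks into its own 15-s
  baseline: a short pulse of height d reads as d·(1 − 1/61), and the
  periodic within-bout oscillation reads about 1.6% high because the
  61-sample window anti-correlates with the 1-Hz oscillation. Rectified
  sums therefore track injected ground truth to within ~2% for drift
  timescales of 10 min or more, not to machine precision; this is a
  property of the published pipeline itself, not of the implementation.
* **Boundary effects at hatching.** The baseline window straddles the
  hatch discontinuity for the last ~7.5 s before the crop point, which can
  add one short spurious bout and ~0.5% to the neurogenic sum. Cropping
  removes everything from the hatch time onward; the pre-hatch leakage is
  documented rather than silently filtered.
* **FFT conventions.** Rectangular taper by default (the most literal
  segment FFT); amplitudes `2|X_k|/N`, Nyquist bin halved (unpaired);
  Parseval's relation per window holds to 1e-6 relative and is tested.
* **Ties and degenerate inputs.** Equal hatch-step candidates resolve to
  the earlier time. All-tied samples short-circuit Kruskal-Wallis to
  H = 0 (the tie correction would otherwise divide by zero), and Dunn's z
  is 0 when its standard error vanishes.

## Statistics

The gate declares a sample "normal" only when all four tests
(D'Agostino-Pearson K2, Anderson-Darling, Shapiro-Wilk, Lilliefors/KS)
fail to reject at α = 0.05 — a single rejection routes to nonparametric
tests; samples with n < 8 are "indeterminate" and routed nonparametrically.
Two-group comparisons use Welch's t (parametric) or Mann-Whitney — exact
by enumeration when min(n) ≤ 8 without ties, the tie-corrected normal
approximation otherwise — with plain Bonferroni over the number of
parallel phase comparisons. Multi-group comparisons use Welch's ANOVA plus
the Brown-Forsythe F* as omnibus tests followed by Dunnett T3 pairwise
comparisons (parametric branch), or Kruskal-Wallis followed by Dunn's z
with Bonferroni (nonparametric). Dunnett T3's family adjustment uses the
studentized-maximum-modulus tail under the independence approximation
`1 - (2F_t(|t|, df_Welch) - 1)^m`; the proprietary reference
implementation's exact SMM quadrature is not reproduced, and the
approximation is anti-conservative only negligibly at the family sizes
used here. Tests are two-sided unless a direction is configured.

The qPCR equations are the standard ones: efficiency `E = d^(-1/s)` from a
dilution-series slope — the printed form of this equation is typeset
ambiguously in common sources, and this reading is the one that yields the
canonical E ≈ 2 at the textbook slope — flagged against the usable band
[1.9, 2.2], and fold change `2^ΔCT_goi / 2^ΔCT_ref` with
`ΔCT = CT_control − CT_mutant`, which is invariant to uniform CT shifts.

## Problem sizes and test scaling

The test suite generates everything it needs at run time: oracle
equivalence uses 100 random traces of 20,000 samples and 100 stacks of 50
frames; phenotype checks use cohorts of 12 embryos per genotype at the
full 8-h, 4-Hz recording length; statistical calibration uses 10,000 null
replicates at n = 15 per group. The compressed-timeline preset used in
unit tests (phases at 16/17/19 hAEL) keeps per-test cost low while
preserving every structural feature of the default presets.

## Known limitations

* AVI/MJPEG input is not supported; frame stacks are read from multi-page
  TIFF (or traces from delimited tables). MJPEG quantisation tolerance is
  therefore untested here.
* ROI parsing accepts rectangles only (ImageJ `.roi`/`RoiSet.zip` or the
  JSON dialect); automatic embryo segmentation and invaded-ROI detection
  are out of scope — exclusions are per-label annotations with reasons.
* Phase boundaries are fixed developmental times, not detected onsets.
* The generator's cohorts underdisperse relative to real embryos (see
  above); use them to validate machinery, not to estimate power.
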