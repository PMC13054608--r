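---
title: "Frequency-tagged statistical learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-tagged statistical learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freqtag)
```

## The paradigm and what the package computes

Infants watch a continuous stream of eight shapes presented at 6 Hz. The
shapes are organised in four deterministic doublets: within a doublet the
transitional probability (TP) from the leading to the trailing shape is 1,
while after a doublet each of the other three doublets follows with TP 1/3.
An infant that individuates the pair structure shows EEG responses not only
at the 6 Hz stimulus rate but also at the 3 Hz doublet rate. Familiarization
runs in extended blocks of 24 s (144 shapes) with 2-s fades; only the
triggered 20-s core (120 shapes) is analysed. Sessions comprise at least 8
blocks and move to a looking-time test once 120 s of cumulative looking are
reached (at most 15 blocks).

The analysis chain implemented here is:

1. **Spectra.** A rectangular-window FFT of each 20-s core gives a one-sided
   amplitude spectrum with 0.05-Hz bins, so every tagged frequency falls
   exactly on a bin centre and a steady sinusoid suffers no leakage. The
   SNR at a bin is its amplitude divided by the mean amplitude of the 10
   surrounding bins (5 per side, skipping the 2 adjacent bins).
2. **Valid blocks.** A block is analysed only if the 6-Hz SNR exceeds 2 in
   at least one of ten a-priori medial occipital channels and the infant
   looked for at least 7 s of the core. Participants contribute only if they
   have at least two valid blocks at a timepoint. Valid blocks are
   renumbered consecutively, truncated at order 8, and block order and
   looking time are grand-mean centred.
3. **Harmonics and ROI.** One-sided Wilcoxon signed-rank tests against
   SNR = 1 select the harmonics carrying signal; multiples of 6 Hz can never
   be attributed to the doublet response. Permutation maximum statistics
   threshold group-mean SNR topographies, and the ROI is the set of
   electrodes significant at both 3 and 6 Hz in at least two timepoints.
4. **Aggregation.** SNR is averaged over ROI electrodes, then over the
   selected harmonics, giving one base and one doublet SNR per block. The
   learning index is `log(doublet SNR) - log(base SNR)`.
5. **Models.** Random-intercept linear mixed models describe log SNR across
   blocks and timepoints; one-sample t-tests with Holm correction and a
   linear model linking the learning index to the behavioural novelty
   preference complete the chain.

## The generative model behind the synthetic cohorts

No public dataset accompanies this design, so the package ships a simulator
whose defaults are the fitted models themselves; every analysis can then be
validated as a generative/analytic round trip.

Per retained block of subject $i$ at timepoint $t$ the two log outcomes are

$$y^{(b)}_{ijt} = X_{ijt}\beta^{(b)} + u^{(b)}_i + e^{(b)}_{ijt}, \qquad
  y^{(d)}_{ijt} = X_{ijt}\beta^{(d)} + u^{(d)}_i + e^{(d)}_{ijt},$$

with the design comprising timepoint, centred block order, their
interaction, and centred looking time. The default fixed effects are the
fitted estimates of the base model (intercept 0.302, T2 0.100, T3 0.002,
order -0.024, looking 0.029 s^-1, T2xorder 0.001, T3xorder 0.025) and the
doublet model (0.152, 0.060, 0.083, -0.013, 0.018, -0.006, 0.027); variance
components are 0.013/0.043 (base) and 0.010/0.042 (doublet).

The learning index is never drawn separately: it is identically
$y^{(d)} - y^{(b)}$. Its variance components (0.006 intercept, 0.066
residual) are induced by correlating the two outcomes,
$\operatorname{cov}(u^{(b)}, u^{(d)}) = (0.013 + 0.010 - 0.006)/2 = 0.0085$
and $\operatorname{cov}(e^{(b)}, e^{(d)}) = (0.043 + 0.042 - 0.066)/2 =
0.0095$. The three reported models are thus mutually consistent under one
joint distribution; the implied learning-index fixed effects (e.g. T3 =
0.083 - 0.002 = 0.081) agree with the separately fitted values (0.082)
within printed rounding.

Cohort structure: 30 subjects at T1, a random 27 of them at T2, 23 of those
at T3 (80 sessions). Blocks fail the valid-block filter independently with
probability 0.2358, matching the long-run valid fraction of 76.42%; half of
the failures are behavioural (core looking drawn uniformly below 7 s) and
half electrophysiological (6-Hz response suppressed). Core looking time of
attended blocks is `7 + 13 * Beta(2.6, 0.8)` seconds, giving extended-block
looking near 19 s and predominantly 8-block sessions, in line with the
reported session statistics. These two shapes are the package's choice of a
realistic attention profile; they are not fitted to data.

Test-phase behaviour follows a per-timepoint linear link from the subject's
mean learning index to the expected preference score with slopes -0.969
(T1), 1.672 (T2), 4.421 (T3) and intercepts -0.070, 0.692, 0.484 (the
fitted simple slopes and marginal intercepts), plus Gaussian noise
(preference residual SD 0.75, per-trial SD 1 s; both package choices, as no
residual scale is reported). Trial looking times are truncated to the 7-s
trial window. Because the generative behaviour model carries no subject
effect, the random intercept of the brain-behaviour model typically
estimates to zero and the fit falls back to an ordinary linear model -- the
same degeneracy observed in the real analysis.

### Waveform synthesis ("full mode")

Fast mode emits block features directly from the models above; full mode
additionally synthesises 128-channel, 20-s waveforms at 1000 Hz. Noise is
built in the frequency domain: independent complex Gaussian coefficients
whose expected one-sided amplitude follows `scale / f + floor` (1/f
exponent 1 by default) — the minimal spectrum that reproduces an off-peak
SNR floor of about 1. Signal is added as bin-centred sinusoids at the base
harmonics (6/12/18/24 Hz) and doublet harmonics (3/9/15/21 Hz) with relative
harmonic weights (6 Hz dominant for the base response; 9 Hz strongest for
the doublet response, as observed in the younger groups) and an occipital
gain map: gain 1 on the seven-electrode ROI cluster, 0.5 on the remaining
a-priori occipital electrodes, 0 elsewhere. The map is normalised to its
maximum, so rescaling all gains changes nothing.

Amplitudes are calibrated by inverting the Rice mean: the expected modulus
of signal-plus-complex-noise at the tagged bin is set to the target SNR
times the local noise floor (`calibrate_amplitude()`, relative tolerance
1e-6). One refinement matters: the SNR denominator is the *mean of 10
neighbouring amplitudes*, and the expectation of its inverse exceeds the
inverse of its expectation by a factor of about 1.0264 (delta expansion for
the mean of 10 Rayleigh variables). Block synthesis divides the calibration
target by this factor so that the *measured* ROI log SNR is centred on the
requested target. The same small-sample ratio bias is why, under pure
noise, the per-block SNR statistic has expectation about 1.027 rather
than 1.

## Statistical choices and their consequences

**Amplitude, not power.** The SNR is operationally defined as an amplitude
ratio; the package follows that definition throughout. DC and Nyquist are
left unhalved in the one-sided spectrum; this never touches the analysed
bins and is fixed purely for reproducibility.

**Edge bins are masked, not shrunk.** Bins whose ±2..±6 neighbourhood
leaves the spectrum are undefined (`NA`) rather than estimated with a
shorter neighbourhood, which would bias the statistic; all analysed
frequencies are interior anyway.

**Wilcoxon aggregation.** The harmonic-selection tests need one SNR value
per subject and frequency, but the channel set and block aggregation behind
them are not fixed by the protocol. The package averages each subject's
amplitude spectra over their valid blocks and the ten a-priori occipital
channels *before* taking the SNR ratio. Averaging first shrinks the
denominator's inverse-mean bias from ~2.7% (single block/channel) to
~0.05%, and Monte-Carlo calibration confirms the test then holds its
nominal level (false-positive rate ~5% at alpha = .05 with 20 subjects),
whereas averaging per-block ratios would reject in roughly half of
noise-only cohorts. The exact signed-rank null is used up to n = 25 and the
continuity-corrected normal approximation above, matching the cohort sizes
straddling that boundary. Subject-level ROI topographies are built the same
way (per electrode).

**Maximum statistics are a localisation device, not a calibrated test.**
The permutation scheme replaces each subject's topography with a unit
topography with probability 1/2 and thresholds the observed group mean at
the 95th percentile of the permuted maxima. Because the replacement halves
both the elevation *and* the spread of the maximum, the threshold tracks
roughly half of the observed peak elevation. With strong occipital signal
this behaves sensibly -- the threshold sits far above the noise floor and
only genuinely responsive electrodes clear it, which is how it is used
here. Under a global null, however, the procedure does not control
family-wise error at the nominal 5%: simulation with noise-only
topographies (20 subjects, 6 blocks, 128 electrodes, 1000 permutations, 500
datasets) yields a family-wise rejection rate around 0.66. The package
implements the scheme as specified (that behaviour is a property of the
method, faithfully reproduced) and the corresponding calibration check in
the acceptance suite documents the discrepancy rather than hiding it.
Empirical quantiles use linear interpolation (R type 7); the identity
assignment is not force-included in the null (immaterial at 10000 draws);
significance is strict inequality.

**Stepwise model selection.** Comparisons refit by ML and accept a step
when the LRT p-value is below .05 or the AIC drops by more than 2. Note
that with the default effect sizes the timepoint-by-order interaction of
the doublet model has a 2-df LRT non-centrality near 5, i.e. roughly 50%
power per cohort -- detection is well above chance but by no means certain
in any single cohort, and the package's tests assert exactly that.

**Degrees of freedom.** Mixed-model t-tests use Satterthwaite approximation
(via lmerTest); with ~470-490 residual degrees of freedom this matches
Kenward-Roger to reported precision, and exact Kenward-Roger is out of
scope. Confidence intervals are Wald (estimate ± 1.96 SE) for every
reported coefficient. Treatment coding with T1 as reference matches all
printed contrasts. Reported fits use REML; comparisons use ML.

**Centering.** Block order and looking time are centred at one
dataset-wide grand mean over retained rows (the protocol does not stratify
the centering); per-timepoint centering is available as an option. The
centering constants are recorded in the block table's metadata.

## Problem sizes used in the tests

The shipped test-suite sizes are the package's trade-off between
Monte-Carlo resolution and a test run of a few minutes: 1000 generated
blocks (1.43e5 transitions) for the TP law-of-large-numbers checks, 3000
blocks for slot-frequency uniformity, 40-60 synthesised waveform blocks for
SNR-target recovery (Monte-Carlo SE ~0.015 log units), 100 replicate
cohorts for fixed-effect recovery (Monte-Carlo SE ~0.002-0.003 per
coefficient), 500 datasets x 1000 permutations for the family-wise
calibration, and 1000 replicates for the Wilcoxon level. The acceptance
script regenerates its quantities from scratch at the same sizes.

## What the simulator does and does not emulate

It emulates: the longitudinal cohort sizes and monotone attrition, the
valid-block incidence, per-block looking behaviour and its covariate effect
on log SNR, persistent subject effects with the reported intraclass
correlations, the spectral signature of frequency tagging (harmonics, an
occipital topography, a 1/f noise floor), and the timepoint-specific
brain-behaviour link.

It does not emulate: artefacts (blinks, motion) or their upstream cleaning,
channel interpolation, volume conduction or realistic source geometry,
autocorrelation of residuals across blocks beyond the random intercept (no
information on it is available), drifting attention within a block, or
coder noise in the looking-time records. Passing tests therefore show that
the analysis chain is correct and recovers the generative structure it
assumes -- not that the chain is robust to every pathology of real infant
EEG.

## Known limitations

* The family-wise miscalibration of the unit-replacement permutation scheme
  under a global null, described above.
* The looking-time coefficient of the base model is reported inconsistently
  at its source (0.485 in text vs 0.029 in the table, possibly a
  standardised vs raw discrepancy); the simulator defaults to the tabled
  value and exposes the alternative (`looking_coef_alt`) for sensitivity
  analyses.
* Whether the test phase's novel pairs preserved within-doublet position is
  not documented; the generator uses position-preserving recombination (a
  derangement of trailing shapes), which isolates pairing novelty. The
  reverse-transition asymmetry of familiar test trials is likewise not
  modelled.
* Fast-mode cohorts carry no spectra, so harmonic selection and ROI
  derivation run only in full mode; fast-mode pipelines use the configured
  sets.
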