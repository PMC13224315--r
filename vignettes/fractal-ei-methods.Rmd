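---
title: "Methods: spectral Hurst estimation and excitation-inhibition modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral Hurst estimation and excitation-inhibition modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractalEI)
```

## The scientific problem

Resting BOLD fluctuations show long-range temporal correlations: their power
spectral density falls off approximately as a power law, $S(f) \propto
f^{-\beta}$. The Hurst exponent $H$ summarises this scaling — $H = 0.5$ is
uncorrelated noise, $0.5 < H < 1$ indicates persistent (long-memory)
dynamics, and values in $(1, 2)$, under the *extended Hurst* convention,
indicate a non-stationary, fractional-Brownian-motion-like signal.
Computational models predict that the balance of cortical excitation and
inhibition (E:I) shapes these scaling properties, and magnetic resonance
spectroscopy (MRS) offers an in vivo proxy for that balance: the ratio of
Glx (glutamate + glutamine) to GABA+ (GABA + macromolecules) in a single
voxel. This package implements the full analysis chain for testing an
H–E:I association in a two-condition (rest vs. movie-watching),
within-subject design, together with a synthetic-data generator rich enough
to exercise and validate every stage.

## The Hurst estimator

For each voxel time series the pipeline:

1. estimates the PSD by Welch's method — the series is divided into
   `n_segments` (default 8) segments with `overlap_fraction` (default 0.5)
   overlap, each segment is mean-centred, tapered, and its periodogram
   averaged;
2. regresses $\log_{10}$ power on $\log_{10}$ frequency by ordinary least
   squares over **all** bins with positive frequency and positive power, and
   takes the spectral index $\beta$ as minus the slope;
3. converts to the Hurst exponent via $H = (1 + \beta)/2$, and classifies
   the signal as fGn for $0 < H < 1$, fBm for $1 < H < 2$ (with $H = 1$
   deterministically assigned to fBm), and out-of-range otherwise.

Numerical choices the estimator pins down explicitly:

* **Segment sizing.** $L = \lfloor N / ((n_\mathrm{seg}-1)(1-o) + 1)
  \rfloor$, so the segments exactly tile the series at the requested
  overlap (for 8 segments at 50% this is $\lfloor 2N/9 \rfloor$); trailing
  remainder samples are dropped. A sizing error names the minimum usable
  $N$ when segments would fall below 8 samples.
* **Taper.** A periodic Hann window per segment. A taper is needed to
  control spectral leakage, which otherwise flattens steep $1/f$ spectra
  and biases $H$ downward.
* **Detrending.** Segment-mean removal only — the minimal intervention,
  since upstream preprocessing is assumed to have rendered the signal
  approximately stationary.
* **Fit range.** The full positive-frequency axis up to Nyquist. The zero
  frequency bin is excluded because $\log 0$ is undefined; this is forced,
  not a tuning choice. The regression uses base-10 logs (the slope is
  base-invariant; the stored intercept is base-10).
* **Normalisation.** One-sided density scaled so that
  $\sum_k S(f_k)\,\Delta f \approx \operatorname{Var}(x)$ (Parseval, up to
  taper correction).

Voxels with constant, all-zero or non-finite series, or with unusable
spectra, carry the sentinel value 0 in Hurst maps, and the ROI mean (grey
matter ∩ MRS voxel) averages only finite non-zero voxels. NaN values read
from external maps are coerced to the sentinel with a logged count.

The estimator is validated against exact simulation: `simulate_fgn()`
draws fractional Gaussian noise by circulant embedding of the closed-form
autocovariance
$\gamma(k) = \tfrac{\sigma^2}{2}(|k-1|^{2H} - 2|k|^{2H} + |k+1|^{2H})$,
with the embedding grid the next power of two $\ge 2(N-1)$. The embedding
of the fGn covariance is nonnegative definite; a materially negative
eigenvalue therefore signals a broken covariance and raises a hard error
(with the instruction to double the grid) rather than clipping, which
would silently corrupt the ground truth. `simulate_fbm()` is its exact
cumulative sum. On simulated data the full estimator recovers $H^* \in
\{0.6, 0.7, 0.8\}$ to within $\pm 0.05$ (100 series of length 1024),
is monotone in $H^*$, estimates white noise at $H = 0.50 \pm 0.03$
(200 series of length 480), and places cumulative sums of fGn($0.7$) near
$H = 1.7$ in the fBm regime. The full-spectrum fit does carry a small
positive bias for large $H$ (about $+0.03$ at $H^* = 0.8$), the price of
using all frequencies instead of a low-frequency band; band-restricted
fits are deliberately out of scope.

## Multi-echo combination

With multiple echoes, per-voxel signal decays as
$S(\mathrm{TE}) = S_0 e^{-\mathrm{TE}/T_2^*}$. `fit_monoexponential()`
solves the exact log-linear regression first and refines it by damped
Gauss–Newton; the refinement is accepted only while it reduces the sum of
squared residuals (relative tolerance $10^{-8}$), so the result is never
worse than the analytic initialisation. Echoes with non-positive signal
are dropped so each voxel is fitted on its maximum number of reliable
echoes; fewer than two reliable echoes, or fitted $T_2^*$ outside the
physiological window $(1, 500)$ ms, invalidates the voxel. With exactly
two echoes the closed-form solution is returned. Echo combination uses
contrast-to-noise weights $w_i \propto \mathrm{TE}_i
e^{-\mathrm{TE}_i/T_2^*}$ normalised to sum to one — the standard weighting
for optimal multi-echo combination, recorded in the output metadata;
voxels without a valid $T_2^*$ fall back to the unweighted echo mean, with
the count logged. Default echo times are 12.2, 35.352 and 58.504 ms.

## Quality control

* **Framewise displacement** is the Power-style sum of absolute backward
  differences of the six rigid-body parameters, rotations converted to mm
  on a 50 mm sphere. FD is invariant to constant offsets in any parameter.
* **Exclusions.** A subject is removed if any condition's mean FD exceeds
  0.15 mm, or any MRS scan's water-peak FWHM exceeds 10 (interpreted as Hz
  by spectroscopy convention, overridable). Both thresholds are strict
  inequalities, so a value exactly at threshold is retained.
* **Consensus masks.** The consensus of the subjects' MRS voxel masks is a
  strict majority vote (a voxel tied at exactly half the masks is
  excluded); agreement is summarised as the mean Dice coefficient between
  each mask and the consensus. Dice of two empty masks is defined as 1
  (identical), flagged as degenerate.

## The mixed-effects model

The cohort model is a Gaussian random-intercept model fitted by REML
(via lme4):

$$H \sim \mathrm{E{:}I} + \mathrm{Condition} + \mathrm{meanFD} +
\mathrm{FWHM}_\mathrm{sLASER} + \mathrm{FWHM}_\mathrm{MEGA} +
\mathrm{FreqShift}_\mathrm{sLASER} + \mathrm{FreqShift}_\mathrm{MEGA} +
(1 \mid \mathrm{Subject})$$

Condition is coded with movie as the reference level so the reported
coefficient is the rest-vs-movie contrast. Fixed-effect $t$ statistics and
95% CIs use the residual-df approximation $\mathrm{df} = n_\mathrm{obs} -
n_\mathrm{fixed} - n_\mathrm{subjects} + 1$ — simple, recorded in the
output, and adequate for the balanced two-condition design
(Satterthwaite/Kenward–Roger corrections are out of scope). A consequence
worth knowing: with only 6 subjects the full 8-term fixed design leaves
non-positive residual df, so `fit_lmm()` refuses it and `run_pipeline()`
falls back to the core scientific terms (E:I + Condition) for such small
cohorts, logging the reduction. Marginal and conditional $R^2$ follow the
Nakagawa–Schielzeth decomposition (variance of fixed-effect predictions
over total, with the intercept variance added for the conditional value).
Collinearity is screened with classical VIFs on the fixed design; a
rank-deficient design is an error naming the collinear columns.

Exploratory contrasts are paired Student's $t$-tests (Cohen's $d$ for
paired data defined as mean difference over the SD of differences) and
Pearson correlations with $t$-based two-sided p-values. No
multiple-testing correction is applied to these post hoc tests; raw
p-values are reported without significance labels.

**Power** is estimated by simulate-and-refit: cohorts are drawn from the
generative model with the E:I coefficient forced to the target effect size,
refitted, and the fraction of replicates with $p < \alpha$ for that
coefficient reported with an exact binomial 95% CI. Replicates that fail to
refit are excluded and counted, never imputed. At effect size 0 the
procedure is calibrated to $\alpha$; with the default generative spec,
power is non-decreasing over effect sizes 0.07, 0.14, 0.21 (H units per
unit E:I).

## What the synthetic generator emulates — and what it does not

`generate_cohort_table()` draws, per subject, a random intercept on $H$
(SD 0.1) and, per condition, metabolite concentrations from normal
distributions truncated at zero (Glx $9.84 \pm 1.06$ rest / $10.04 \pm
0.79$ movie mM; GABA+ $5.48 \pm 0.77$ / $5.23 \pm 0.71$ mM), then sets

$$H = \beta_0 + \beta_\mathrm{Rest}\,\mathbb{1}[\mathrm{rest}] +
\beta_\mathrm{EI} \cdot \mathrm{E{:}I} + u_\mathrm{subject} + \varepsilon$$

with defaults $\beta_0 = 1.05$, $\beta_\mathrm{Rest} = -0.07$,
$\beta_\mathrm{EI} = 0$ (a null E:I effect; nonzero values are the knob for
power experiments) and residual SD 0.05. Within-subject correlation of
metabolites across conditions is induced by a shared subject-level offset
whose SD is 50% of the between-subject SD — a free parameter, since no
empirical within-subject correlation is available to copy. QC covariates
are drawn from plausible uniform ranges (mean FD 0.05–0.20 mm, FWHM 6–11)
wide enough to exercise the exclusion rules, and frequency shifts from a
zero-mean normal (SD 1).

`generate_phantom_subject()` builds a cubic "brain" of concentric
compartments — outer grey-matter shell, white-matter layer, CSF core — on
a default $16^3$ grid with 480 frames at TR 1.5 s. Voxel signals are exact
fGn with tissue-specific $H$ (GM 0.9 > WM 0.7 > CSF 0.5) on
tissue-specific baselines; echo $i$ is the base signal scaled by
$e^{-\mathrm{TE}_i / T_2^{*,\mathrm{tissue}}}$ plus optional white noise.
The MRS voxel is a jittered cube in the posterior grey-matter shell (the
jitter exercises the Dice consensus machinery), and motion is a random
walk on the six rigid-body parameters. Condition effects are imposed on
the grey-matter target $H$ at study-simulation time.

The generator reproduces the *statistical* structure of the study — not
real physiology. It has no hemodynamic response, no physiological noise or
spatial autocorrelation, no spectral line shapes (metabolite concentrations
are emitted directly, skipping spectral fitting entirely), and its
geometry is a toy. Passing tests therefore demonstrate that the estimators
and models recover known ground truth under the study's sampling
conditions; they cannot certify behaviour on acquired data with artefacts
the generator does not model.

## Problem sizes used in validation

The validation suite uses: 200 white-noise series of length 480 for
calibration; 100 fGn series of length 1024 per $H^*$ for recovery; 200
cohort replications of 200 subjects for CI coverage; 1000 simulate-refit
replicates per effect size for power; and one full synthetic study of 6
subjects × 2 conditions × 3 echoes × 480 frames on a $16^3$ grid for the
end-to-end run. These sizes give Monte-Carlo error comfortably below the
tolerances being checked while keeping the suite quick on a laptop.

## Known limitations

* The full-spectrum log–log fit is mildly biased for strongly persistent
  signals (see above); alternative estimators (DFA, wavelets, maximum
  likelihood) are intentionally not implemented.
* The residual-df approximation is anti-conservative relative to
  Satterthwaite for severely unbalanced designs; the pipeline targets the
  balanced two-condition case.
* The echo-combination weights are the standard contrast-to-noise form;
  acquisitions combined with a different convention will differ slightly.
* The generator's free parameters (within-subject metabolite correlation,
  residual SD of $H$) have no empirical anchor and are documented
  defaults, not estimates.
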