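---
title: "Models and methods behind fgrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fgrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgrkit)
library(dplyr)
```

fgrkit analyses mouse studies of fetal growth restriction (FGR) in which
growth-restricted and wild-type pups coexist within litters — the situation
created by the placental-specific *Igf2* knockout (P0), where a litter from
one dam contains both genotypes and a maternal treatment (here sildenafil
citrate, SC, in the drinking water) is applied at the litter level. This
vignette explains the models the package implements, the calibration of its
synthetic cohort generator, and the numerical and design choices a
maintainer should know about.

## The study design being emulated

Each dam carries one litter of ~8 pups at E18.5; genotype (WT / P0)
varies *within* litters while treatment (water / SC) varies *between*
litters. Four cells result: WT-water, WT-SC, P0-water, P0-SC. Endpoints are
fetal and placental weight, anthropometrics, umbilical Doppler velocimetry,
and radiotracer-based placental transport (Kmf). Because pups of one dam are
correlated, the litter — not the pup — is the independent statistical unit;
every inferential procedure in the package respects that.

## The synthetic cohort generator

`generate_cohort()` is first-class, tested code, not a test fixture. Its
defaults *are* the study conditions the package targets: 23 water and 19 SC
litters, mean litter sizes 8.0 and 8.6, 52% WT pups per litter, and the cell
means of `default_calibration()` (fetal weight 1.20/1.25 g WT, 0.94/1.02 g
P0; placental weight 0.092/0.097, 0.065/0.072 g; plus crown-rump length and
abdominal/head circumference).

Pup endpoints follow a two-level Gaussian model. For a pup of cell
$(g, t)$ in litter $l$:

$$y = \mu_{g,t} + \sigma_{g,t}\left(\sqrt{f}\, b_l + \sqrt{1-f}\, z\right),
\qquad b_l, z \sim N(0,1),$$

so the marginal SD of every cell equals its calibrated $\sigma_{g,t}$ and a
fraction $f$ (`variance_split`, default 0.5) of the variance lies between
litters. The litter factor $b_l$ is shared by all pups of a litter across
genotypes, which is what makes litter-level inference necessary downstream.

**Where the SDs come from.** Published group summaries report litter-level
SEMs but no pup-level SDs, so two SDs are back-derived and the rest chosen
to be consistent with the printed SEMs:

* WT-water fetal SD **0.1034 g**: inverting the 5th-centile formula
  $\text{threshold} = \mu - 1.645\,\sigma$ with $\mu = 1.20$ g and the
  reported threshold 1.03 g gives $\sigma = (1.20 - 1.03)/1.645$.
* P0-water fetal SD **0.1334 g**: the reported 25% of untreated P0 pups
  above 1.03 g gives $\sigma = (1.03 - 0.94)/z_{0.75}$ with
  $z_{0.75} = \Phi^{-1}(0.75) \approx 0.6745$.
* Each genotype's two cells share a fetal SD; placental (0.012 g) and
  anthropometric SDs are set so litter-mean SEMs at the default litter
  counts land near the printed 0.002 g / 0.1–0.5 mm values.

With the 50/50 split and ~4 pups per genotype per litter, the implied SEM of
a P0 cell mean over 19 litters is
$\sqrt{\sigma^2 f + \sigma^2 (1-f)/\bar m}/\sqrt{19} \approx 0.024$ g,
consistent with the printed 0.02 g. These derivations are calibration, not
measurement; the split between the two levels is a documented choice
exposed as `variance_split`.

**Other generator choices.** Litter sizes are rounded normal draws
(SD 1.2 pups, clamped at 1): a Poisson litter size would imply an SEM of
~0.7 pups over 19 litters, far above the printed 0.2–0.3, so a
lower-dispersion model matches the reported design better. Negative
endpoint draws are resampled at the pup level (keeping the litter effect);
negative plasma concentrations are clamped to zero with a warning — the two
rules keep marginal means close to calibration while respecting positivity.
Fetal and placental pup deviations are independent given the litter by
default (`fp_correlation` exposes the alternative). Exsanguination times
are drawn per dam, uniform on 1–5 min, matching the tracer protocol window.

**What the generator does not emulate.** Only an E18.5 snapshot — no
gestational time course, no resorption or embryo loss, no maternal
physiology, no genotype-dependent Doppler differences, and Gaussian
endpoints throughout. Passing tests therefore demonstrate that the
*machinery* is correct under the calibrated conditions, not that real data
meet those conditions.

## Clearance kinetics

Maternal plasma tracer concentration after a bolus follows a one-phase
exponential, $C(t) = C_0 e^{-kt}$, fitted by `fit_disappearance()` with
log-linear starting values refined by Levenberg–Marquardt least squares
(`minpack.lm`), $k$ bounded at zero. The model is two-parameter by default;
a plateau term is available (`plateau = TRUE`) because some curve-fitting
conventions include one, but it is off by default. Fits with
$r^2 \le 0.6$ are *flagged*, not discarded: the quality rule gates group
summaries, and what to do with failing dams is left to the analyst because
no refit procedure is established. The default is a single pooled fit over
all supplied dams, mirroring the pooled construction of such curves in
practice; a per-dam fit is a flag away.

Unidirectional maternofetal clearance for a fetus with tail-corrected
accumulation $N_x$ (dpm) at time $x$:

$$K_{mf} = \frac{N_x}{W \int_0^x C_0 e^{-kt}\,dt}
         = \frac{N_x}{W \cdot \frac{C_0}{k}(1 - e^{-kx})}
\quad \left[\frac{\text{dpm}}{\text{g} \cdot \text{dpm·min/µl}}
      = \frac{\text{µl}}{\text{min·g}}\right],$$

with $W$ the placental wet weight; dividing instead by fetal weight gives
delivery per gram of fetus, and omitting the weight gives total clearance
(µl/min). The closed-form integral uses the $C_0 x$ limit when
$k < 10^{-12}$ and is verified against adaptive quadrature to $10^{-8}$
relative error. The tail-tip correction
$N_x = N_\text{raw} / (1 - \text{fraction})$ assumes the label is uniformly
distributed in fetal mass — the existence of a correction is established,
its formula is this package's choice.

## Growth centiles

`fit_weight_distribution()` offers the field's histogram route — a Gaussian
curve fitted through bin counts (default bin width 0.05 g, ~6–8 bins per SD
at observed scales) by nonlinear least squares — and a direct moments route;
the two agree within 2% on clean Gaussian samples and the histogram route
falls back to moments with a warning when the histogram is degenerate. The
5th-centile threshold is $\mu - 1.645\sigma$ (`z_critical` defaults to
`qnorm(0.95)`), taken from the *untreated wild-type* reference cell.
"Below the centile" means strictly below; weights exactly at the threshold
count as above, matching clinical usage (configurable via `boundary`).
Covariate-adjusted or skewed (LMS-style) centiles are out of scope.

## Doppler indices

The synthetic waveform is a half-rectified raised cosine on a diastolic
baseline, starting in diastole so every systolic peak is interior to the
recording; its analytic cycle mean is $EDV + (PSV - EDV)/\pi$. The shape is
a modelling convenience with controllable max/min/mean, not a physiological
claim. `detect_cycles()` finds systolic peaks as maxima of contiguous
excursions above `min + prominence × amplitude` (prominence default 0.2,
robust at the generator's noise levels), discards excursions truncated by
the recording edge, and delimits cycles peak-to-peak — $n$ peaks give
$n-1$ full segments, and fewer than 3 segments is an explicit error because
a reportable measurement requires at least 3 cardiac cycles. Per cycle,
PSV is the maximum, MDV (≡ EDV; both names denote the minimum) the minimum,
MV the trapezoidal time average; the pulsatility index is
$PI = (PSV - MDV)/MV$. Averaging over cycles happens *before* the PI
ratio by default — matching a formula applied to single summary values —
with the mean of per-cycle PIs reported alongside; the two differ by <1% on
low-noise traces. Cycles corrupted by maternal breathing have no published
operational exclusion rule, so none is guessed; the per-cycle table lets an
analyst apply their own.

## Litter-aware inference

The reference analysis for such designs is a mixed model with litter as a
random effect followed by a sequential Šidák comparison. fgrkit implements
the inference itself rather than delegating it: pup records are collapsed to
litter × genotype means (`litter_summaries()`), and `permutation_test()`
permutes at the level at which randomisation occurred — treatment labels
across whole litters (a litter never splits), genotype labels within
litters. The two-sided p-value uses the add-one rule
$p = (1 + \#\{|T^\ast| \ge |T|\})/(1 + n_\text{perm})$, exact under
exchangeability of the permuted unit, with default
$n_\text{perm} = 9999$ and a mandatory seed. This litter-summary
permutation is the primary inference; a GLMM (e.g. `lme4::lmer`) remains
available to the analyst as an independent benchmark — the package's tests
use it exactly that way — but REML estimation is deliberately not
reimplemented here, and no link/family beyond the Gaussian litter-summary
view is assumed. The interaction p-value permutes residuals of the additive
litter-summary model, a standard approximation since no exact interaction
permutation exists for unbalanced two-factor designs.

"Sequential Šidák" is implemented as the step-down variant: order the $m$
raw p-values ascending, set
$\tilde p_{(i)} = 1 - (1 - p_{(i)})^{\,m - i + 1}$, enforce monotone
non-decrease along the ordered sequence, and return in input order. The
exact variant is a documented choice; the name alone does not pin one down.

## Numerical choices and degenerate inputs

* Decay and Gaussian fits initialise deterministically (log-linear
  regression; sample moments) so results are reproducible without RNG.
* $k = 0$ and $\sigma = 0$ limits are handled analytically, not by the
  optimiser.
* Constant velocity traces, all-zero concentrations, fewer than 3 plasma
  samples, fewer than 3 cardiac cycles, empty groups, and zero placental
  weights all raise explicit errors or per-record error rows — a pipeline
  run never silently drops a stage.
* All stochastic functions take an explicit seed and restore RNG state
  (`withr`), so `run_pipeline()` reruns byte-identically from its config.

## Problem sizes used in the test suite

Large-sample checks use $10^5$ pup weights (centile recovery, tail
proportions, marginal variance), 200 replicates for noisy rate-constant
recovery, and 1000 null datasets × 999 permutations for the type-I error of
the litter permutation test — sizes at which Monte-Carlo error is
comfortably inside the asserted tolerances while the whole suite runs in
well under a minute of compute per heavy block.

## Worked pipeline run

```{r pipeline, eval = FALSE}
report <- run_pipeline(cohort_config(seed = 2026), n_perm = 999)
report$centiles
glance(report$comparisons$fetal_weight)
```

At this calibration the pipeline reproduces the qualitative findings the
defaults encode: ~74% of untreated P0 pups below the WT-water 5th centile
falling to ~55% under SC, a strong genotype effect with a P0-specific
treatment effect on fetal weight, and Kmf per gram placenta flat across
cells (the generator applies one true clearance to all cells, so any
between-cell difference in *total* clearance reflects placental weight).

## Known limitations

Calibration SDs are back-derived, not measured; the permutation surrogate
answers a slightly different question than a REML mixed model (exact
exchangeability inference on litter summaries versus likelihood inference
on pups); the Doppler stage analyses clean synthetic waveforms, not
ultrasound envelopes; and the dosing module is plain arithmetic in fixed
units (mg/ml, ml/day, g), with no interspecies pharmacokinetic scaling.
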