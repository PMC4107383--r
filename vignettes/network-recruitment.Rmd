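---
title: "Measuring task-dependent recruitment of intrinsic brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring task-dependent recruitment of intrinsic brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netrecruit)
library(dplyr)
```

## The analysis in one paragraph

Intrinsic (resting-state) brain networks — the default mode network, the
frontoparietal control networks, visual and motor networks, and so on — are
usually characterised by their spontaneous activity, but they are also
recruited, or suppressed, by cognitive tasks. `netrecruit` quantifies that
recruitment. Given a set of fixed network spatial maps $X_M$ (one 3-D
z/t-valued image per network) and a subject's 4-D BOLD series $Y$, the
package (i) rescales $Y$ to percent signal change, (ii) forms each network's
activity timecourse as the voxelwise dot product
$a_M(t) = \sum_v X_M(v)\, Y(t, v)$, (iii) fits an ordinary-least-squares GLM
of $a_M$ on HRF-convolved task regressors with drift and the six rigid-body
motion parameters in the baseline, yielding a recruitment coefficient
$\beta_{M,N,P}$ and t-score per network $M$, condition/contrast $N$ and
participant $P$, and (iv) performs group inference on those $\beta$s:
one-sample t-tests with percent-of-sample sign consistency, and a two-stage
brain–behaviour regression (stepwise covariate selection, then Huber robust
regression of $\beta$ on a performance score). A slice-parity screen
identifies and removes motion "stripe" artifacts from ICA decompositions
before any of this happens. Because no suitable public dataset pairs all of
these ingredients, the package ships a seeded synthetic-cohort generator
with known ground truth; every stage of the chain is validated against it.

## The generative model behind the synthetic cohort

The generator emulates a block-design task fMRI study of `cohort_size`
subjects. For subject $P$ with performance score $s_P$ (accuracy %, uniform
on `performance_range`), the true recruitment amplitude of network $M$ under
condition $N$ is

$$\beta^{true}_{M,N,P} = b_0 + b_1 s_P + \varepsilon_{M,N,P},
\qquad \varepsilon \sim \mathcal N(0, \sigma_s^2),$$

with `intercept` $b_0$, `slope` $b_1$ and `subject_sd` $\sigma_s$. The raw
BOLD series is a multiplicative percent modulation of a constant baseline
$B$:

$$Y(t, v) = B \left(1 + \frac{1}{100}\Big(\textstyle\sum_M X_M(v)
\sum_N \beta^{true}_{M,N,P}\, \tilde s_N(t) + \eta(t, v)\Big)\right),$$

where $\tilde s_N$ is the condition-$N$ boxcar convolved with the canonical
HRF and then mean-centred, and $\eta$ is white (optionally AR(1)) Gaussian
noise with per-voxel standard deviation `noise_sd` in percent-signal-change
units. Three design choices here deserve justification, because they are
what make the closed loop exact rather than approximate:

* **Multiplicative signal.** BOLD contrast physically rides on a baseline
  intensity; writing the signal as a percent modulation means the
  percent-signal-change rescaling in the analysis path inverts the
  generative transform *exactly*. An additive signal on top of a baseline
  would make the per-voxel temporal mean signal-dependent, so division by
  it would distort amplitudes at the $10^{-3}$ level — enough to swamp the
  package's $10^{-6}$ recovery contract.
* **Mean-centred regressors in generation.** Only the fluctuation of the
  convolved boxcar is identifiable once each voxel's temporal mean has been
  removed; centring $\tilde s_N$ in the generator keeps every voxel's
  temporal mean exactly $B$. The GLM fits the *uncentred* regressor plus an
  intercept, so the fitted slope is unaffected — the DC offset lands in the
  intercept, where it belongs.
* **Unit-energy, disjoint network blobs.** `gen_component_maps()` places
  Gaussian blobs (width `blob_sigma`, default 1.5 voxels) at seeded random
  integer centres, truncates them at $3\sigma$, enforces a centre
  separation that makes supports pairwise disjoint, and normalises each map
  to $\sum_v X_M(v)^2 = 1$. The dot-product projection is then an
  orthogonal-projection coefficient: projecting a noiseless subject and
  fitting the GLM returns $\beta^{true}$ to machine precision, with no
  cross-talk between networks. Real ICA maps overlap and are not
  unit-energy, so on real data the recruitment betas are in
  (percent-signal-change × map-weight) units and comparable across
  subjects, not across differently scaled maps — exactly as in practice.

Defaults mirror a desk-scale version of a typical acquisition: a
20×20×10-voxel grid at 3 mm, TR 2 s, 150 frames, a 20 s on / 20 s off block
task, 38 subjects, performance uniform on [60, 100] (an accuracy-like
score whose median sits in the 80s), and white noise at `snr = 5`, where
`noise_sd = mean(|beta|)/snr`. The spatial scale is deliberately small so a
full cohort simulates in seconds; nothing in the analysis path depends on
grid size. What the generator does **not** emulate: vascular and
physiological noise, spatial autocorrelation of noise, overlapping
networks, scanner drift beyond what the Legendre baseline absorbs, and
motion that actually corrupts the data (the motion table is a small random
walk used to exercise the QC and baseline-regression paths). Passing tests
therefore demonstrate correctness of the estimators, not robustness to
every pathology of real EPI data.

## Stripe-artifact screening

Head motion under interleaved slice acquisition leaves "stripes": ICA
components whose spatial maps alternate sign with slice parity. Since such
patterns are not biologically plausible, screening is deliberately liberal:
a component is flagged when the absolute Pearson correlation between its
spatial map (over in-mask voxels) and any mean-centred ±1 slice-parity
pattern exceeds 0.05, and flagged components are subtracted from the data
via their outer-product reconstruction. Two conventions were genuinely
open and are resolved as follows: the correlation is **spatial** (the
artifact's signature is a spatial striping, and a temporal criterion would
not distinguish it from task-locked signal), and **absolute** correlation
is used (a stripe is equally implausible in either sign). The in-data mask
defaults to voxels carrying any map weight, since synthetic data has no
anatomical mask. Motion QC passes a dataset only if every frame stays
within 3 mm translation and 3° rotation of the first frame; the reference
frame is a convention (any fixed reference differs only by an offset).

## The GLM

The HRF is the canonical double-gamma — a positive gamma lobe with mode at
6 s minus an undershoot lobe with mode at 16 s at a 6:1 amplitude ratio —
sampled at the TR and normalised to peak 1, so a unit-height block keeps
interpretable amplitude units after convolution. The kernel is pluggable
(`hrf_kernel()` is an ordinary function argument of `build_design()`), and
the generator and the fitter share it, so model mismatch is an experiment
one can construct, not a hidden default. The baseline holds Legendre drift
polynomials up to order 2 (slow scanner drift; the order is configurable)
plus the six motion parameters. Estimation is OLS with
$t = \hat\beta/\mathrm{se}$ on $n - \mathrm{rank}(Z)$ degrees of freedom
and no autocorrelation correction — the variance of recruitment betas is
consumed by *between-subject* analyses, where within-subject
autocorrelation affects all subjects alike. Designs are rank-checked at
construction, and the failure message names the collinear columns
(all-zero motion tables are the classic trigger).

## Group inference and the brain-behaviour regression

Per cell (network × condition/contrast), `group_ttest()` gives the
one-sample t against zero and the percent of the sample with positive
$\beta$ — the sign-consistency number that distinguishes "significant
because consistent" from "significant because a few large subjects".
`consistency_table()` assembles the full grid and adjusts p-values across
cells by Benjamini–Hochberg; `autoplot()` renders it with colour
saturating at $|t| \ge 5$.

The brain–behaviour analysis is two-stage. First, stepwise selection over
the candidate pool — performance, age, sex, education, handedness, head
coil, session order, mean trial duration — with entry at coefficient
$p < 0.05$ and removal at $p > 0.10$ (forward selection with backward
elimination, ties broken by declaration order; for single-column terms the
coefficient-t and partial-F conventions coincide). Mean trial duration
enters the *candidate* pool by default, with a `force_in` option for
analysts who prefer it unconditionally present. Second, the selected
covariates are refit by Huber M-estimation (IRLS; weights 1 inside
`tuning = 1.345` robust-scale units, `c/|r/s|` outside; scale re-estimated
each iteration as $\mathrm{median}(|r|)/0.6745$; convergence when the
largest coefficient change falls below $10^{-8}$). Standard errors come
from the asymptotic covariance of the final weighted solve,
$\hat\sigma_w^2 (X'WX)^{-1}$ with $\hat\sigma_w^2 = \sum w_i r_i^2/(n-p)$ —
adequate at the cohort sizes this design targets, and validated for
near-nominal interval coverage in the test suite. As tuning
$\to \infty$ the estimator collapses to OLS, which the tests assert at
$c = 10^6$. Binary covariates are coded 0/1; education is an integer
ordinal.

Recruitment variability is compared between performance groups by a
median split with ties assigned to the *upper* group (the high group is
"at or above" the split value), reporting each group's sample sd of
$\beta$ and a Brown–Forsythe test: a one-way F on absolute deviations from
the group medians with df $(1, n-2)$, robust to non-normal betas. A plain
variance-ratio F test (df $(n_1-1, n_2-1)$) is available as an option. The
Brown–Forsythe choice is worth a note: published reports of this style of
split sometimes quote an F with denominator df near $n - 2$, which no
two-group variance-ratio test produces (that would have df
$(n_1-1, n_2-1)$); the deviation-based one-way F is the standard test with
that df structure, and it is what this package implements.

## Numerical conventions and edge cases

* Voxel indices are 0-based in world-coordinate arithmetic; world
  coordinates come from origin + index × voxel size; the slice axis is the
  third data axis unless overridden.
* Map resampling is nearest-neighbour by default (weight-preserving, no
  new values invented), trilinear optionally; it is the identity on a
  matching grid, and disjoint world extents raise a geometry error.
* Percent-signal-change scaling zeroes voxels whose temporal mean
  magnitude is below $10^{-8}$ (and counts them); applying it twice is a
  state error, and `run_subject()` scales only unscaled input.
* Projection uses the *unthresholded* map; the $t \ge 4$ cut
  (`display_mask()`) is a display convention only.
* HRF convolution is a direct sparse sum, not FFT, so frames before any
  stimulus are exactly zero and an impulse reproduces the kernel samples
  bit-for-bit.
* Stepwise selection drops constant candidates with a warning, treats
  degenerate (perfect-fit) p-values as never-enter/never-leave, and warns
  when $n$ is not comfortably larger than the candidate count.
* `robust_fit()` declares convergence immediately when the residual scale
  collapses below $10^{-12}$ (noise-free data), and errors with its
  iteration trace if `max_iter` is exhausted.
* All generator randomness flows from one master seed through a fixed
  splitting rule (`master seed × subject index → subject seed`), so
  cohorts are bit-reproducible regardless of evaluation order.

## Problem sizes used in validation

The test-suite simulations are sized for completeness of coverage at
interactive runtimes: projection oracles on 8×8×4×50 grids; 500-replicate
bias checks at signal-to-noise 1 on 8×8×4 grids; 100 replicate cohorts of
$n = 40$ for slope recovery; 250 replicates per arm for the null
selection-rate comparison; 2000 replicates for variance-test calibration;
and 100 twelve-subject cohorts on 10×10×6 grids for the deactivation
contract. The acceptance script (`scripts/acceptance.R`) runs a full
38-subject cohort at the default 20×20×10 scale end to end.

## Known limitations

* The projection is a fixed-map template analysis (one spatial regression
  per network, independently); it is not dual regression's joint spatial
  fit, and overlapping maps will leak shared variance into each other's
  timecourses.
* OLS ignores temporal autocorrelation; per-subject t-scores are
  anti-conservative on strongly autocorrelated data (the recruitment
  *betas*, which downstream analyses consume, are unbiased regardless).
* The stripe screen assumes the artifact is parity-locked along one axis;
  oblique or multi-band artifacts need their own patterns (the `patterns`
  argument accepts `interleave-k` variants).
* Stepwise selection inherits all classic caveats of data-driven covariate
  selection; the package reports the selection trace so analysts can see
  what entered and left, and the null entry rate is part of the test
  suite rather than an assumption.

## A compact end-to-end example

```{r example, eval = FALSE}
cfg <- sim_config(cohort_size = 12, n_networks = 2, snr = 5,
                  master_seed = 7)
cohort <- gen_cohort(cfg, slope = -1, intercept = 105, subject_sd = 5)
recruit <- run_cohort(cohort$volumes, cohort$maps, cfg$design,
                      subjects = cohort$subjects)
consistency_table(recruit, term_type_filter = "contrast")
performance_regression(filter(recruit, term_type == "contrast"),
                       cohort$subjects, "C_1")
```
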