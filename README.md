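# netrecruit

Task fMRI studies often ask a network-level question: how strongly does a
cognitive task recruit (or suppress) each of the brain's intrinsic
resting-state networks, and does that recruitment track behavioural
performance? `netrecruit` implements the full analysis chain for that
question in R, for researchers who have preprocessed 4-D BOLD data and a
set of fixed network spatial maps (e.g. canonical ICA components), plus a
seeded synthetic-cohort generator so every stage can be validated against
known ground truth without any real scan.

## The method

Given a network spatial map $X_M$ and a subject's BOLD series $Y$ scaled
to percent signal change, the network's activity timecourse is the
voxelwise dot product with each frame:

$$a_M(t) = \sum_v X_M(v)\, Y(t, v).$$

A per-subject GLM of $a_M$ on HRF-convolved task regressors — with
Legendre drift polynomials and the six rigid-body motion parameters
(x, y, z, roll, pitch, yaw) in the baseline — yields a recruitment
coefficient $\beta_{M,N,P}$ and t-score per network $M$, task
condition/contrast $N$ and participant $P$. Group inference then proceeds
in three forms:

* **Activation consistency** — one-sample t-tests of $\beta$ against zero
  per (network, contrast) cell, with the percent of the sample showing
  positive recruitment, assembled into the classic heatmap grid
  (`consistency_table()` + `autoplot()`), BH-adjusted across cells.
* **Brain–behaviour regression** — stepwise covariate selection (entry
  $p < 0.05$, removal $p > 0.10$) over performance, age, sex, education,
  handedness, head coil, session order and mean trial duration, followed
  by Huber robust regression (tuning constant 1.345) of $\beta$ on the
  selected covariates (`performance_regression()`).
* **Variability comparison** — a median split on performance (ties to the
  upper group) with a Brown–Forsythe test of equal $\beta$ variance
  between low and high performers (`variance_split_test()`).

Upstream, `detect_stripe_components()` screens ICA decompositions for
head-motion "stripe" artifacts — spatial maps correlating with ±1
slice-acquisition parity patterns at the liberal threshold $|r| > 0.05$ —
and `remove_components()` subtracts them; `qc_motion()` enforces the
3 mm / 3° motion limits.

## Worked example

Simulate a 12-subject block-design cohort in which true network amplitude
declines with the performance score (slope −1), run every subject through
QC → percent-signal-change scaling → projection → GLM, and examine the
group results:

```r
library(netrecruit)
library(dplyr)

cfg <- sim_config(cohort_size = 12, n_networks = 2, snr = 5,
                  master_seed = 7)
cohort <- gen_cohort(cfg, slope = -1, intercept = 105, subject_sd = 5)
recruit <- run_cohort(cohort$volumes, cohort$maps, cfg$design,
                      subjects = cohort$subjects)

consistency_table(recruit, term_type_filter = "contrast")
#> # A tibble: 2 × 11
#>   network condition        n mean_beta     t    df          p percent_positive
#>   <chr>   <chr>        <int>     <dbl> <dbl> <int>      <dbl>            <dbl>
#> 1 C_1     task_vs_rest    12      26.9  7.82    11 0.00000813              100
#> 2 C_2     task_vs_rest    12      24.9  7.49    11 0.0000121               100
```

Both simulated networks are robustly recruited: mean contrast betas near
26 (percent-signal-change × map-weight units), group t around 7.5–7.8 on
11 df, and 100% of subjects activating in the positive direction. The
brain–behaviour stage recovers the generative performance link:

```r
performance_regression(filter(recruit, term_type == "contrast"),
                       cohort$subjects, "C_1")
#> <performance_fit> C_1 / task_vs_rest, n = 12
#> stepwise selected: performance
#> # A tibble: 2 × 5
#>   term        estimate     se     t            p
#>   <chr>          <dbl>  <dbl> <dbl>        <dbl>
#> 1 (Intercept)  101.    6.91    14.6 0.0000000449
#> 2 performance   -0.955 0.0894 -10.7 0.000000866
```

Stepwise selection keeps only the performance score out of the
eight-covariate pool, and the Huber robust slope of −0.955 ± 0.089
recovers the generative slope of −1. See the methods vignette
(`vignettes/network-recruitment.Rmd`) for the generative model, the
statistical conventions, and the design decisions behind each stage.

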