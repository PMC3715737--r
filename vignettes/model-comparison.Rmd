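---
title: "Disentangling correlated parametric regressors in BOLD GLMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disentangling correlated parametric regressors in BOLD GLMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldmc)
```

## The problem

Model-based fMRI regresses a BOLD time series on the trial-by-trial
predictions of a computational model. When two candidate internal variables
are computed at the same event — the classic case being the reward
prediction error (RPE) of a reinforcement-learning model and the raw reward
outcome (RO), both defined at feedback time — their parametric regressors
are strongly collinear. Fitting both in one GLM then yields unstable
parameter estimates, and testing either regressor alone against baseline
can misattribute function: a region driven almost entirely by RO will also
"activate" for RPE, simply because the two share most of their variance.

`boldmc` implements a model-comparison answer: rather than asking whether a
regressor correlates with a region at all, it asks which of two
equally complex candidate models explains a region's BOLD variance better,
in three algebraically equivalent ways, and checks that the verdicts agree.

## The learning model

The RPE regressor derives from the Rescorla-Wagner rule. With reward
receipt $R_t$ on trial $t$ and predicted value $V_t$,

$$\delta_t = R_t - V_t, \qquad V_{t+1} = V_t + \alpha\,\delta_t,$$

where $\alpha \in [0,1]$ is the learning rate. `rw_trace()` iterates this
exactly; the seven-trial sequence $R = (1,0,0,1,1,1,0)$ with $\alpha = 0.5$
and $V_1 = 0$ gives

```{r}
rw_trace(c(1, 0, 0, 1, 1, 1, 0), alpha = 0.5)$deltas
```

The initial value defaults to $V_1 = 0$, the only choice consistent with a
first-trial prediction error of 1 for that sequence. A delivered reward
produces a positive $\delta_t$ and an omitted one a negative $\delta_t$, so
$\delta$ and $R$ are intrinsically correlated — that correlation is the
entire problem this package addresses. When several stimuli interleave,
`trial_types` gives each its own independently updated value, with an
optional per-stimulus $\alpha$.

## From events to regressors

`build_regressor()` turns an event table into a sampled regressor: each
event contributes a stick (zero duration) or boxcar (positive duration) of
height equal to its modulation, the stimulus function is convolved with a
canonical double-gamma HRF (peak at ~5 s, undershoot around 16 s, unit
peak so that modulations carry the amplitude; `canonical_hrf()`), and the
result is decimated to the output grid. Convolution runs on an internal
0.1 s grid, with onsets snapped to the nearest fine-grid sample, so that
output sampling (default 1 s) does not quantize onset timing.

Two conventions deserve explanation:

* **Modulations are mean-centered across events before convolution**
  (`center_modulations = TRUE`). This is the standard treatment of
  parametric modulators in fMRI design construction, and it is what makes
  the correlation between two sparse-event regressors equal the Pearson
  correlation of their modulation vectors. Without centering, the long
  stretches of baseline between events pull the time-series correlation
  toward the *uncentered* modulation correlation (about 0.72 for the
  reference scenario instead of 0.89). For a main-effect regressor whose
  absolute amplitude matters (e.g. a single unit impulse), set
  `center_modulations = FALSE`.
* **Standardization uses the population convention** (divide by $n$)
  throughout, in `zscore()` and in the simulator's noise scaling, so that
  documented examples are exact rather than convention-dependent.

Candidate regressors must be z-standardized before fitting: beta magnitude
otherwise reflects regressor scaling as well as explained variance, and the
cross-model beta comparison becomes meaningless.

## The three comparison approaches

`orthogonalize()` replaces a regressor by the residual of its least-squares
projection onto other regressors *plus the intercept*; projecting out the
mean makes "zero dot product" and "zero Pearson correlation" the same
statement. The result is deliberately not re-standardized: this preserves
the identity that the serially orthogonalized (last-entered) regressor's
beta equals its beta in the plain, non-orthogonalized full model — its
semipartial, unique-variance contribution.

For candidates $A$ and $B$, `build_designs()` constructs four designs, each
with intercept:

| design | columns | role |
|---|---|---|
| full 1 | $A$, $B\perp A$ | $B$'s unique contribution |
| full 2 | $B$, $A\perp B$ | $A$'s unique contribution |
| reduced A | $A$ | residual variance under $A$ alone |
| reduced B | $B$ | residual variance under $B$ alone |

The two full designs span the same column space (orthogonalization is a
change of basis), so their fitted values and hat matrices coincide; only
the attribution of shared variance differs. The three comparisons are:

1. **Orthogonalized betas** (`compare_orthogonalized()`): compare
   $\hat\beta_{A\perp B}$ from full 2 with $\hat\beta_{B\perp A}$ from
   full 1 — uniquely explained variance against uniquely explained
   variance.
2. **Non-orthogonalized betas** (`compare_nonorthogonalized()`): compare
   the first-entered betas, each of which absorbs the shared variance;
   subtracting the two statistics cancels the shared part, so the verdict
   again reflects unique variance.
3. **Residual variance** (`compare_residuals()`): compare
   $\ln(\mathrm{RSS}/n)$ of the two reduced fits; the better model leaves
   less unexplained variance. Because
   $\mathrm{AIC} = n\ln(\mathrm{RSS}/n) + 2k$ and
   $\mathrm{BIC} = n\ln(\mathrm{RSS}/n) + k\ln n$ are increasing linear
   functions of the log residual variance at fixed $n$ and $k$, the
   equal-complexity ranking by log residual variance is identical to the
   AIC and BIC rankings (`fit_glm()` exposes all three). This approach
   generalizes to unequal model complexities via AIC/BIC, which the other
   two do not.

`run_report()` executes all three on one series and reports agreement of
the non-tie winners plus diagnostics, including the pre-orthogonalization
correlation $r$. When $r^2 > 0.5$ the report carries a warning flag: with
more than half the variance shared, the *comparison* is still valid, but
attributing the shared variance to the winner requires prior scientific
grounds, not statistics.

## Numerical choices and degenerate inputs

* OLS uses QR decomposition with a rank check; rank-deficient designs fail
  with the names of the collinear columns — near-collinearity being the
  package's whole subject, silent pseudo-inverse fallbacks would hide the
  one thing the user must know.
* $k$ counts all columns including the intercept, and `log_res_var` applies
  no degrees-of-freedom correction, matching the AIC/BIC forms above.
* A residual sum of squares at the level of numerical noise
  ($\mathrm{RSS} \le 10^{-12}\,\mathrm{TSS}$) is treated as zero:
  `information_criteria()` and `compare_residuals()` refuse such fits,
  since $\ln \mathrm{RSS}$ is then meaningless (noise-free or overfitted
  input).
* Ties are explicit: margins smaller than `tie_tolerance` (default
  $10^{-6}$ on the standardized-beta scale) are reported as ties rather
  than broken arbitrarily, because the equivalence of the three approaches
  only holds away from ties. Winners compare signed betas by default (the
  positive-loading scenario); `use_abs = TRUE` compares magnitudes for
  signals of unknown sign.
* Orthogonalizing a regressor that lies in the span of its bases (residual
  sd below $10^{-12}$) is an error, as is z-scoring a constant series.

## The ground-truth simulator

`two_region_fixture()` generates the package's reference validation scenario:
a 200 s series at 1 s sampling with 7 zero-duration feedback events at
onsets $10 + 27k$ s ($k = 0..6$). The RO regressor carries the delivery
indicator $(1,0,0,1,1,1,0)$; the RPE regressor carries the Rescorla-Wagner
prediction errors of that same sequence ($\alpha = 0.5$). After convolution
and standardization the two correlate at $r = 0.89$. Region A mixes them
$0.8\,\mathrm{RO} + 0.2\,\mathrm{RPE}$, Region B the reverse, plus i.i.d.
Gaussian noise with standard deviation `noise_sd` times the mixture's sd
(default 0.2 — a noise floor low enough that the 0.6 weight gap is
recoverable on a single 200 s series, while still leaving the raw betas
visibly perturbed). Onset schedule and noise level are configuration
choices of this package, exposed as arguments and recorded in the written
provenance, not facts about any particular experiment. Weights act on
z-scored regressors, so "80%/20%" reads as relative standardized
contribution.

What the simulator deliberately omits: scanner drift and physiological
noise (no high-pass filtering or AR modelling exists in the package
either), temporal-difference-style backward-shifting prediction errors
(learning is trial-level Rescorla-Wagner only), multi-subject variability,
and any group-level inference. Passing validation here therefore shows the
comparison machinery is algebraically and statistically sound under white
noise — not that it is robust to structured fMRI noise.

`simulate_region()` is seeded and bit-reproducible; `two_region_fixture()`
derives Region A's noise from `seed` and Region B's from `seed + 1`.
`simulate_volume()` tiles the two regions into adjacent 3×3×3 voxel blocks
with independent per-voxel noise to exercise the voxelwise path.

## Validation suite sizes

The test suite validates, among others: the closed form
$\delta_t = c(1-\alpha)^{t-1}$ for constant rewards; hat-matrix equality of
the two full designs; the solver against independent normal-equations and
SVD pseudo-inverse oracles (50 random problems); exact recovery of mixture
weights at zero noise; ≥95% majority-model recovery per approach over 100
noise realizations of the two-region scenario; and ≥95% three-way winner
agreement over 100 random mixtures with weight gap ≥ 0.2 at noise sd up to
0.5 — with AIC/BIC/log-residual-variance rank agreement required in all
runs. Series length is 200 samples throughout, matching the reference
scenario.

## Files and command line

`read_events()`/`write_events()` handle BIDS-style `events.tsv`
(`onset`, `duration`, `trial_type`, optional `modulation` defaulting to 1);
`read_series()` reads one-column-per-region TSV; `run_compare()` writes a
sorted-key JSON report (no timestamp, so reruns are byte-identical) and a
flat TSV; `run_voxelwise()` reads a 4D NIfTI plus mask and writes per
approach an integer winner map (0 tie / 1 A / 2 B) and a margin map. The
`boldmc` script in `inst/cli/` exposes `simulate`, `compare` and
`voxelwise` subcommands over a YAML config; see `?cli_main` and
`?read_config`.

```{r, eval = FALSE}
dir <- tempfile()
run_simulate(list(seed = 1), dir)
run_compare(list(events = file.path(dir, "events.tsv"),
                 series = file.path(dir, "series.tsv"),
                 trial_type = "feedback",
                 models = list(A = list(name = "RO", source = "modulation"),
                               B = list(name = "RPE", source = "rw",
                                        alpha = 0.5))),
            file.path(dir, "report"))
```

## Known limitations

The comparison is between two candidates at a time; comparing more models
requires pairwise runs. Only equal-complexity candidates are handled by the
beta-based approaches (the residual-variance route would extend via
AIC/BIC, but the package keeps $k$ equal by construction). Single-series
verdicts are point-estimate comparisons with an explicit tie band, not
significance tests; group-level inference over subjects or voxels is out of
scope beyond the per-voxel winner maps.
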