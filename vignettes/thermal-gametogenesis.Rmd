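---
title: "Modeling thermal suppression of sea urchin gametogenesis"
author: "urchintherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling thermal suppression of sea urchin gametogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Purple sea urchin (*Strongylocentrotus purpuratus*) recruitment in Southern
California collapses during El Niño events even though water temperatures
stay below the lethal limits of larvae and adults. A candidate mechanism is
sublethal: warm autumn–winter conditions suppress gametogenesis, so fewer
mature gametes are produced in the first place. The experimental design this
package emulates exposes adult urchins in replicated mesocosms to either
constant temperatures (10, 13, 16, 17, 18, 20 °C; two mesocosms of 15
animals each) or dynamic trajectories replaying historical El Niño
(21 → 18 °C, seasonal mean 20 °C) and La Niña (18 → 14 °C, mean 16 °C)
temperature profiles (four mesocosms each), then scores each animal's
gametogenic stage (I–IV histology scale, IV = fully mature) and final gonad
mass. A second, split-plot experiment repeats three treatments (constant
10 °C, constant 20 °C, El Niño) on animals from three source populations
(San Diego, Santa Barbara, Sonoma) nested within tanks.

The package provides, as tested and reusable code: the thermal-schedule
generators, a calibrated synthetic-data generator for both designs, the two
Bayesian models (gametogenic stage; gonad mass), bridge-sampling Bayes
factors with simulation-based calibration, and the posterior summaries
(HPD intervals, stage contrasts, relative reductions, Bayesian P values)
in which results are reported.

## Thermal schedules

Constant schedules ramp linearly from ambient (13.3 °C) to target over two
weeks and then hold; ramps are pre-treatment and are excluded from the
analysis window over which the realized mean is computed. The historical
event trajectories are not tabulated anywhere, so `make_event_schedule()`
adopts a minimal two-segment shape: a plateau at the seasonal peak followed
by a constant-rate decline to the final temperature, with the plateau length
solved (by `uniroot`) so the window mean matches the published mean exactly.
Daily steps never exceed 0.5 °C, matching once-daily manual set-point
adjustment; the solver reports infeasibility when the endpoint/mean triple
cannot be reached under that rate bound. One set-point per day is assumed
(no within-day variation).

## The synthetic-data generator

`generating_params()` holds the ground truth. Stage probabilities per
sex × treatment cell are pinned to the study's printed posterior estimates
where available (stage-IV shares: La Niña females 0.89, El Niño females
0.15, La Niña males 0.92, El Niño males 0.44, constant-20 males 0.812,
constant-20 females 0.25). Cells the study does not print numerically
follow its qualitative description: females mature at 10–18 °C (stage-IV
0.80–0.85) and collapse at 20 °C; males are flat (≈0.8) across all constant
temperatures. The probability mass not in stage IV is split I : II : III as
0.2/0.3/0.5 of the remainder in maturing cells and 0.7/0.2/0.1 in
suppressed cells (suppressed females are mostly stage I). These splits are
assumptions, stated here once and not revisited.

Gonad mass is Gamma with a log-link mean: a cubic in mean temperature
(interpolating, at 50 mm diameter, 9.68 g at 10 °C, 12.41 g at 13 °C,
11.84 g at 16 °C and 7.2 g at 20 °C — the anchors implied by the printed
cell means and the printed 42% and 22% decreases), an allometry exponent of
2.5 on test diameter (gonad mass scales a little below body volume; the
study reports only that log diameter was a covariate), offsets for the
event treatments reproducing the printed 7.03 g (El Niño) and 8.69 g
(La Niña), and Gamma shape 10 (coefficient of variation ≈ 0.32). Mesocosm
intercepts are Normal with SD 0.25 on the stage logit scale and SD 0.1 on
the log-mass scale — tank effects of roughly ±10% in mass, a realistic
scale for replicated mesocosm systems. Sexes are assigned Bernoulli(0.5)
(sex ratios are not reported) and diameters are uniform on the reported
range (42.12–69.46 mm; only mean and range are reported). Experiment-2
stage-IV cells are derived from the printed relative reductions versus the
10 °C treatment, and per-cell sample sizes default to 12 animals per
location × treatment (three per tank), a stated assumption.

What the generator does **not** emulate: growth and feeding dynamics,
spawning phenology, mortality, within-mesocosm covariance beyond a scalar
intercept, sex-ratio imbalance, measurement error in staging, or any
food × temperature interaction. Passing recovery tests therefore shows the
*estimators* are correct and calibrated under the assumed generative
structure at the study's sample sizes — not that real data satisfy that
structure.

## The stage model

Stage (I–IV, unordered categorical with stage I as the reference) is
modeled with a multinomial logit. For each treatment type (constant,
El Niño, La Niña) the baseline stage proportions carry a Dirichlet(1)
prior, mapped to the logit scale with its Jacobian; sex and
sex × treatment-type offsets are Normal(0, 2.5) on the logits; and the
response to mean temperature is a Gaussian-process smoother with a squared
exponential kernel over standardized temperature, one latent column per
non-reference stage *and sex*, sharing a single length-scale and scale with
folded-Normal(1, 1) hyperpriors. Sex-specific smooths are essential: only
females collapse at a constant 20 °C, and a shared smooth would smear that
collapse into the male response. Mesocosms contribute a scalar Normal
intercept (half-Normal(0, 1) prior on its SD) added to all non-reference
logits — a tank-level tilt between "immature" and "maturing". Dynamic-
treatment animals enter the smoother at their realized mean temperatures
(20 and 16 °C) *and* carry categorical offsets; the smoother and those
offsets are jointly identified by the constant-treatment animals at the
same means.

Two parameterization choices matter numerically. First, the GP is sampled
non-centered (latent standard normals premultiplied by the kernel
Cholesky), with hyperparameter gradients via Cholesky differentiation —
the centered version exhibited hyperparameter multimodality and divergent
transitions. Second, the likelihood sees the column-centered field: a
constant added to a smooth column and subtracted from the baselines leaves
the likelihood unchanged, and removing that flat ridge (the smooth carries
shape, the baselines carry level) markedly improves mixing. Predictions at
unfitted temperatures use the GP conditional mean draw-by-draw and warn
when extrapolating beyond the fitted range.

The Experiment-2 variant has no smoother (treatment levels are three
categorical cells), adds a scalar source-location intercept with the
folded-Student-t(df 3, scale 0.1) hyperprior on its SD, and keeps tank
intercepts.

## The gonad model

Gonad mass is Gamma with log link. The linear predictor is an orthogonal
cubic polynomial in mean temperature, log test diameter centered at log 50
(so the intercept is the log mass of the 50 mm reporting standard —
uncentered, the intercept–allometry pair is nearly collinear because
diameters span only 42–69 mm), offsets for El Niño and La Niña relative to
constant treatments of the same mean (required by the reported
within-mean contrasts), and mesocosm intercepts. The selected model has no
sex term, as in the analysis it reproduces. Vague priors: Normal(0, 5) on
coefficients, half-Normal(0, 2) on the mesocosm SD, Exponential(0.1) on the
Gamma shape; `gonad_model_spec()` exposes all three scales as a
prior-sensitivity hook. `standardized_mass()` reports the model-implied
mass at 50 mm with mesocosm effects fixed at zero (the population-median
mesocosm), not integrated over — a deliberate reporting convention, stated
here because the two differ under the log link.

## Sampling and convergence

Both models are sampled with Hamiltonian Monte Carlo using analytic
gradients (verified against central finite differences in the tests),
dual-averaging step-size adaptation, a diagonal mass matrix estimated in
Stan-style expanding warmup windows, and leapfrog path lengths jittered
over 8–16 steps. Test mode runs 4 chains × 3,000 retained draws (stage
model; 2,000 for the faster gonad model) after 1,000 warmup iterations —
1,000 warmup because shorter adaptation windows occasionally left a chain
badly adapted in the GP model. The convergence gate applies to the
*reported quantities* (cell stage-IV probabilities, standardized masses):
split-R̂ < 1.01 with zero divergences in test mode, R̂ < 1.001 in paper
mode (4 × 12,000 after 2,000). The full per-parameter R̂ table ships in
every fit's diagnostics; the GP kernel hyperparameters are the
slowest-mixing parameters and can sit above the smoke-run gate while
every reported quantity is well below it. Numerical guards: 10⁻⁶ jitter on the kernel Gram diagonal, rejection
of trajectories entering numerically hopeless regions (|unconstrained
parameter| > 60, kernel Cholesky failure), and an overflow-safe log-sum-exp
in the multinomial likelihood.

## Model comparison

`log_marginal_bridge()` implements the iterative optimal-bridge estimator:
half of each chain moment-matches a multivariate normal proposal on the
unconstrained scale, the other half plus fresh proposal draws feed the
bridge iteration (relative tolerance 10⁻⁸, max 1,000 iterations), and the
Monte Carlo error combines proposal-sample variance with an
AR-spectrum-corrected posterior-sample variance. The estimator is checked
at every test run against two conjugate closed forms
(Dirichlet–multinomial and normal–normal).

The hypothesis-test contrast for stages is the saturated cell pair: full =
sex × treatment cells (treatment, sex and their interaction), null =
sex-only cells, both under the same Dirichlet(1) construction. Because
that pair is conjugate, posteriors are sampled exactly and the
simulation-based calibration of the Bayes factor (datasets simulated from
each model's own prior predictive, or from a pinned effect size; 20 per
generator in routine runs, 200 in full-length runs) is cheap. Per-model
bridge proposal seeds are derived from the fits themselves so
log BF(A, B) = −log BF(B, A) exactly. Verdicts use the conventional bands:
BF > 100 decisive, 10–100 strong, < 1 favors the second model. The
Experiment-2 contrast (does the treatment effect vary by source
population?) is the sex × treatment × location cell model against the
sex × treatment model.

## Summaries

HPD intervals are exact shortest sorted-sample windows (cross-checked in
tests against exhaustive search and against coda). Stage-IV comparisons
are percentage-point differences (89 − 15 → 74); gonad and Experiment-2
stage comparisons are relative reductions (1 − B/A); both are computed
draw-wise, never on posterior means. "Bayesian P" is not defined in the
source analysis, so both conventions are returned: the one-sided posterior
tail probabilities and the two-sided 2·min(P(Δ>0), P(Δ<0)). Split-R̂
follows the split-chain potential-scale-reduction definition with a
constant-chain guard (R̂ = 1 by convention when all draws are identical).

## Problem sizes and runtime

Routine runs use the study's actual design sizes (300 animals, 20
mesocosms for Experiment 1; 108 animals for the split-plot default), which
keep a full stage-model fit to about two minutes and a gonad fit under
half a minute on one core. Large-sample distributional checks in the test
suite use 10,000 animals with random effects disabled (2% tolerance);
calibration checks use 50 replicates through the exact conjugate path.

## Known limitations

* The multinomial (unordered) likelihood discards the ordinality of the
  stage scale; an ordered-logit variant is out of scope.
* The GP smoother has six support points (the distinct design
  temperatures), so "non-parametric" is generous — length-scales much
  shorter than the design spacing are unidentifiable.
* Cell-probability point estimates shrink toward the Dirichlet prior mean
  by ~4/(n+4); at 15–30 animals per sex × cell this is a visible 1–3
  percentage points and is part of the model, not a bug.
* The Experiment-2 full model (location interactions) is fit with 54 cell
  parameters on ~108 animals; its Bayes factor is prior-sensitive, which
  is exactly why the calibration harness exists.
* `simulate_from_fitted()` for stage models fills gonad mass with nuisance
  values; it calibrates stage-model comparison only.
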