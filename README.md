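# urchintherm

Bayesian analysis of sublethal thermal suppression of gametogenesis in the
purple sea urchin (*Strongylocentrotus purpuratus*), built around two
mesocosm experiments: a thermal gradient plus simulated El Niño / La Niña
seasonal trajectories (300 animals, 20 mesocosms), and a split-plot
common-garden comparison of three source populations. The package is for
quantitative ecologists who want the full pipeline — generative simulation,
hierarchical Bayesian fits, Bayes-factor model comparison, posterior
summaries — as tested, reusable R code that runs without any external data.

## What it implements

**Gametogenic stage** (histology score I–IV, IV = mature) is modeled as an
unordered multinomial logit with stage I as reference. For animal *i* in
sex *s*, treatment type *t*, mesocosm *m*, with standardized mean
temperature *x*:

    eta_k(i) = b_{t,k} + male_i (beta_k + gamma_{t,k}) + f_{s,k}(x_i) + u_m
    P(stage = k) = softmax(0, eta_2, eta_3, eta_4)_k

with Dirichlet(1) priors on the baseline stage proportions softmax(0, b_t),
Normal(0, 2.5) sex offsets, a per-sex, per-stage Gaussian-process smoother
f with squared-exponential kernel (shared length-scale and scale,
folded-Normal(1,1) hyperpriors), and scalar mesocosm intercepts
u_m ~ Normal(0, sigma). **Gonad mass** is Gamma with log link: an orthogonal
cubic in mean temperature, log diameter centered at log 50 mm, El Niño /
La Niña offsets, and mesocosm intercepts; `standardized_mass()` reports the
curve for a 50 mm animal. Both models are sampled by Hamiltonian Monte
Carlo with analytic gradients; convergence is gated on split-R̂. Marginal
likelihoods come from an iterative optimal-bridge estimator with a
moment-matched multivariate-normal proposal, giving Bayes factors
(BF > 100 decisive, 10–100 strong, < 1 favors the alternative) and a
simulation-based calibration harness that simulates datasets from full and
null models and checks the Bayes factor favors the generator.

The synthetic-data generator is calibrated so the ground truth reproduces
the study's printed posterior estimates (e.g. stage-IV shares of 0.89 /
0.15 for La Niña vs El Niño females, standardized masses of 11.84 g at
16 °C and 7.2 g at 20 °C), making parameter recovery directly comparable
to the published numbers. See `vignette("thermal-gametogenesis")` for the
full model and calibration account.

## Worked example

```r
library(urchintherm)

params <- generating_params("exp1")          # paper-calibrated truth
data   <- simulate_experiment1(params, exp1_design(), seed = 1)

fit  <- fit_stage_model(data, stage_model_spec("exp1"), seed = 2)
p_ln <- predict_stage_probs(fit, "F", "la_nina", 16)[, "stage4"]
p_en <- predict_stage_probs(fit, "F", "el_nino", 20)[, "stage4"]

round(mean(p_ln), 2)                         # 0.88
round(mean(p_en), 2)                         # 0.25
stage_contrast(p_ln, p_en)$summary[, 1:4]
#         quantity     mean hpd90_lower hpd90_upper
#   stage_contrast 63.22967    48.50909    77.74804
```

Read: with a generating truth of 89% of La Niña females in stage IV versus
15% under El Niño (a 74-point decline), this particular simulated dataset
realized its El Niño females on the high side, and the fit recovers a
posterior-mean decline of 63 percentage points with a 90% HPD of ±15 —
the truth sits inside the interval, and the interval width matches the
published uncertainty scale. At ~30 animals per sex × treatment cell,
single-dataset point estimates genuinely wobble by 5–10 points; the test
suite's calibration checks quantify exactly that.
`fit_gonad_model()` + `standardized_mass()` do the analogous recovery for
gonad mass, and

```r
full <- fit_stage_cells(data, stage_cells_spec("sex_treatment"))
null <- fit_stage_cells(data, stage_cells_spec("sex"))
bayes_factor(full, null)
# <model_comparison> full vs null
#   log ML: -242.831 vs -240.973;  log BF = -1.858 (BF = 0.156), <1 (favors second model)
```

is the treatment-effect hypothesis test: the saturated 16-cell model pays
a large Occam penalty, and across simulated datasets at this design size
the log Bayes factor ranges from about −2 (this seed) to +27, decisive in
the typical case. `calibrate_bf()` makes that systematic — simulating
datasets from each model's own prior (or from a pinned effect size) and
verifying the Bayes factor favors the generating model. `run_pipeline()`
chains the whole thing (simulate → fit → compare → summarize) into a run
directory with a reproducibility manifest.

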