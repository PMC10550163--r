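---
title: "Models and methods in facetrait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in facetrait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

When faces are reduced to animated 68-point landmark clouds, recognising the
expressed emotion becomes hard, and both *where* an observer chooses to look
and *who* the observer is may shape the judgement. facetrait implements the
full analysis pipeline for a forced-choice expression-recognition experiment
with mouse-contingent aperture viewing: only a small region around the cursor
is visible, so the cursor trace is a record of conscious observational
behaviour. Three questions are modelled separately:

* **A.** Does dwell on the upper / middle / low face predict which of the six
  expressions (happiness, sadness, anger, disgust, surprise, fear) the
  observer selects?
* **B.** Do Big-Five traits (TIPI-type scores on a 1–7 scale) predict the
  selection?
* **C.** Do traits predict the observational behaviour itself?

# Preprocessing cursor traces

Cursor samples are translated into video coordinates by subtracting the
stimulus origin. Each in-canvas sample deposits an isotropic Gaussian kernel
(sd 10 px, truncated at 4 sigma, unit mass) and the per-session sum is the
attention density. The face bounding box — the union box of all 68 landmarks
over all frames, so the partition is fixed within a session — is split top to
bottom into *upper : middle : low = 1 : 0.8 : 0.6* bands. The observation
weight `G_g` of band `g` is the fraction of total accumulated density inside
that band; mass outside the box is discarded, so the triple lies in `[0, 1]`
with sum at most 1.

Two conventions the data themselves do not fix, and what we chose:

* **Normalisation.** Weights are fractions of the session's total density
  (the zero-inflated beta support requires `G` in `[0, 1)`). The raw band
  masses and the out-of-box fraction are emitted alongside for inspection.
* **Per-sample mass.** Every sample counts equally; with a regular sampling
  clock this equals time weighting. Kernels are deposited at the rounded
  pixel and cropped at the canvas edge, so a sample hugging the border can
  lose a little of its unit mass — irrelevant at the face, which sits in the
  canvas centre.

# The three models

## Choice models (A and B)

The response is six indicator variables `y_k` (`y_k = 1` iff expression `k`
was selected). Each indicator is Bernoulli with

```
logit P(y_k = 1) = alpha_k + sum_g x_g beta_kg + r_subj[i,k] + r_stim[j,k]
```

where `x` is the weight triple (variant A) or the five raw, uncentred trait
scores (variant B). The likelihood is the *product of six independent
Bernoulli terms*, not a softmax: the six probabilities need not sum to one.
A categorical (softmax) likelihood is available behind a flag
(`choice_loglik(..., categorical = TRUE)`) for sensitivity analysis, never as
the default. Fits are blocked by presented expression: one independent fit
per condition (`fit_conditions()` loops over the six).

Priors: normal(0, sd 10) on intercepts and fixed effects (sd 10 is the same
as variance 100, so all three analyses share it), gamma(10, 10) on the
participant and stimulus random-effect scales, normal(0, scale) on the
effects. Random effects are one per (participant x response) and one per
(stimulus x response) — the minimal structure consistent with "random
effects of the participant and the stimulus video"; intercepts are
per-response only.

## Zero-inflated beta behaviour model (C)

Each region weight is exactly zero when the region was never visited, else a
value in (0, 1); a zero-inflated beta captures both:

```
G ~ (1 - q) * delta_0 + q * Beta(phi * mu, phi * (1 - mu))
logit q  = alpha^Z_k + sum_l beta^Z_kl p_l + ranefs   (was the region seen?)
logit mu = alpha^B_k + sum_l beta^B_kl p_l + ranefs   (how much, if seen)
```

`q` is explicitly the probability of a *nonzero* observation. The shapes
satisfy `a + b = phi` identically, and `E[Beta(a, b)] = mu`. `phi` has no
stated prior in the source analyses; we use gamma(shape 2, rate 0.1), weakly
informative on positive support, shared across the three areas by default
(area-specific via `shared_phi = FALSE`). Weights at the closed boundary are
clamped to `[1e-6, 1 - 1e-6]` before evaluation.

# Inference

The posterior is sampled with the package's own No-U-Turn sampler over the
exact log-posterior with analytic gradients: random effects are
non-centred (`r = sd * z`), scales and `phi` are sampled on the log scale
with Jacobians, step size is tuned by dual averaging (target acceptance
0.8) and a diagonal mass matrix is estimated in doubling windows during
warmup. The default schedule is 4 chains x 2000 iterations with 1000
warmup, i.e. 4000 retained draws; "iterations" counts warmup, which is the
only reading that makes the retained total 4000.

Summaries:

* **Split-R̂** per parameter (chains halved, classical potential scale
  reduction); 1.1 is the convergence cut-off. Fits exceeding it are
  reported with a warning, never silently dropped.
* **95% HDI**: the shortest window of `ceiling(0.95 n)` order statistics,
  ties broken toward the lowest lower bound; chains are pooled first.
* **Significance**: a fixed effect is significant iff 0 is strictly outside
  its HDI (0 on the boundary counts as included). Tables list the
  fixed-effect (slope) coefficients only; random effects are monitored but
  not tabulated.

# The synthetic study and what it does (not) show

The generator emulates the study design end to end: `n` participants with
independent truncated-normal(4, 1.2) trait scores on [1, 7] (final scores
directly — item-level responses are never used downstream); 8 actors x 6
expressions = 48 landmark videos (a fixed 68-point template, 17 jaw + 10
brow + 9 nose + 12 eye + 20 mouth points, ~200 x 250 px in a 600 x 800
canvas, 2500 ms at 50 ms frames, sinusoidal expression-specific
displacement — mouth opening for happiness/surprise/fear — and small rigid
actor perturbations); region weights drawn from the ZIB truth; choices
drawn from the choice truths; and optionally cursor traces that dwell at
band centres with 4 px jitter so that preprocessing recovers the intended
triple within L1 0.05.

**Forced choice vs independent Bernoullis.** The likelihood treats the six
responses as independent, but a participant selects exactly one label. The
generator resolves this by sampling the label from the softmax
(multinomial-logit) distribution over the six linear predictors — the
standard forced-choice link, under which equal predictors give 1/6 each and
a saturated predictor wins almost surely. Posterior-predictive reports use
the same convention (and also emit the unnormalised per-response Bernoulli
means). One consequence worth stating plainly: under any single-choice
generation the marginal of `y_k` is not exactly `logit^-1(mu_k)` — the
normalisation shifts intercepts by roughly `-log sum(exp(mu))` and
attenuates slopes by ~10% at our effect sizes. Parameter-recovery checks
therefore target the slope coefficients, whose attenuation is far below
posterior spread at desk scale, not the intercepts.

Default ground truth (the study conditions of every seeded test): matching
response intercept 1.2, others -1.2 (about 70% accuracy); variant-A slope
1.0 of the middle weight on the matching response and -0.8 on the next
response's upper weight; variant-B slope 0.8 of agreeableness on choosing
happiness and of extraversion on choosing surprise; ZIB truth with
`q = logit^-1(1.4, 1.4, 1.0)` (most regions visited), conditional means
(0.38, 0.33, 0.25), `phi = 10`; all random-effect scales 0.3. Because the
three region weights are drawn independently, a triple occasionally sums
above 1; model fitting uses the weights as drawn, and only trajectory
realisation rescales them.

What passing tests do *not* show about real data: the generator has no
item-level measurement error in traits, no fixation dynamics or saccade
structure in the traces (dwell points with jitter only), no actor-specific
expressiveness beyond rigid perturbation, and choices truly come from the
fitted model family — so recovery results certify the software and the
inference, not the behavioural theory.

# Numerical choices and problem sizes

* Gradients of both model families are analytic and tested against central
  finite differences to 1e-4.
* NUTS: max tree depth 10, divergence threshold 1000 on the joint
  log-density, initialisation retried up to 20 times for a finite target.
* ZIB quadrature normalisation holds to 1e-8 across a (q, a, b) grid.
* Convergence checks in the test suite fit one presented-expression
  condition of a 20-participant x 48-session study with the full 4 x
  2000/1000 schedule (~1 minute); recovery/calibration checks run 5 + 3
  seeded replicates at 15 participants with 2 chains x 1000/500, and the
  end-to-end trait-effect check runs 2 replicates at the 40-participant
  study scale — sizes chosen so the whole suite stays desk-scale while
  leaving the binomial 3-sigma acceptance bands meaningful. The
  acceptance script fits all six conditions at 20 participants with the
  full schedule.

# Known limitations

* The HDI assumes a unimodal pooled posterior (shortest single interval).
* The independent-Bernoulli likelihood is kept for fidelity; it is not a
  generative model of forced choice, and the categorical flag exists
  precisely to probe that gap.
* Confidence ratings are carried through the data model but never modelled.
* No model comparison (WAIC/LOO) and no joint fit across conditions or
  parts; fits are deliberately blocked the way the headline tables are.
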