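---
title: "Models and methods behind devaltms"
author: "devaltms authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind devaltms}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The experiment this package models

`devaltms` implements the computational analysis of a two-day
outcome-devaluation experiment with network-targeted transcranial magnetic
stimulation (TMS). On Day 1, participants learn to discriminate pairs of
visual stimuli in which one stimulus predicts a food odor (sweet or savory)
and the other predicts clean air. On Day 2, they rate odor pleasantness,
complete a pre-meal choice test, eat a meal that selectively satiates one
of the two odors, and then complete a post-meal choice test with no odor
delivery. Each participant repeats this two-day unit in three sessions
with fresh stimuli, receiving inhibitory continuous theta-burst
stimulation (cTBS) or sham either before Day 1 learning or before the
Day 2 meal, yielding the three within-participant conditions cTBS–sham
(CS), sham–cTBS (SC), and sham–sham (SS). Stimulation targets a lateral
prefrontal site belonging to either an anterior-OFC or posterior-OFC
functional network (a between-participant factor). Resting-state scans
follow every TMS application, plus one unstimulated baseline ("null")
scan, giving seven connectivity sessions per participant.

The package provides, as tested tidyverse-style functions: the
deterministic task-design generators, a synthetic-cohort simulator with
the statistical structure the analysis assumes, a hierarchical Bayesian
Rescorla–Wagner model of discrimination learning, the mixed-effects
behavioral inference stages, array-level connectivity construction, and a
participant-conditioned variational autoencoder (cVAE) that quantifies
stimulation-induced deviation of connectivity patterns in latent space.
No neuroimaging download is required: everything runs end-to-end on the
synthetic cohort.

# Task design

One session's discrimination task uses 12 cue pairs: two stimulus sets
(A, B) crossed with the two odor categories, three pairs per combination,
24 distinct abstract stimuli. Each of five runs presents every pair twice
with left/right positions swapped (24 trials per run). The pre-meal choice
test has 30 trials, all from set A: 3 sweet-vs-air, 3 savory-vs-air, and
9 sweet-vs-savory unique pairs, each shown twice with sides swapped. The
post-meal test has 60 trials drawn from both sets. The per-set composition
of the post-meal test is not itemized in the design description we mirror;
we make set B parallel set A (3 + 3 + 9 unique pairs, twice each), which
reproduces the printed total of 60 and treats the sets as exchangeable.

Condition orders are counterbalanced over the six permutations of
{CS, SC, SS}. At 48 participants the default allocation is fully balanced
(8 per order); `make_session_plans(realized = TRUE)` reproduces the
9/7/8/8/8/8 allocation observed in the study cohort after dropout. When
the cohort size is not divisible by six, the remainder orders are taken
from a Latin-square sequence of the six permutations so that every
condition still occupies every session position within ±1. All
randomization is Fisher–Yates shuffling under seeds derived from
`(base seed, participant, session, run)` through a fixed 31-bit string
hash (`derive_seed()`), which makes every schedule bit-reproducible while
decorrelating streams.

# Hierarchical Rescorla–Wagner model

On each trial of the discrimination task, only the odor-predictive
stimulus carries a learned value $w$, initialized at 0.5 and updated on
every presentation toward the delivered outcome (coded 1):

$$w_{i+1} = w_i + \alpha\,(1 - w_i),$$

so after $n$ presentations $w = 1 - 0.5\,(1-\alpha)^n$ in closed form.
Responses are Bernoulli draws of the pre-update value,
$\mathrm{Resp}_i \sim \mathrm{Bernoulli}(w_i)$, with $\mathrm{Resp}=1$
when the odor-predictive stimulus is chosen. Because the outcome does not
depend on the response, the value trajectory is deterministic given
$\alpha$, and the likelihood factorizes over trials.

Learning rates are hierarchical: pair-level rates
$\alpha_{j,c,p} \sim \mathrm{Beta}(a_{j,c} k_j,\,(1-a_{j,c})k_j)$ around a
subject-session mean $a_{j,c}$, with
$a_{j,c} \sim \mathrm{Beta}(\mu_c K,\,(1-\mu_c)K)$,
$\mu_c \sim \mathrm{Beta}(8,2)$ per session, and concentrations
$K, k_j \sim \mathrm{Gamma}(\mathrm{shape}=1,\,\mathrm{rate}=0.1)$. We use
the mean/concentration parameterization $\mathrm{Beta}(m\kappa,(1-m)\kappa)$
throughout: it makes $a_{j,c}$ the mean learning rate, as the narrative
description requires, and is valid for all parameter values, whereas the
literal form $\mathrm{Beta}(m\kappa, 1-m\kappa)$ breaks down once
$m\kappa \ge 1$. The literal reading remains available via
`fit_hierarchical_rw(prior_reading = "literal")` for comparison on small
problems.

## Sampling

`fit_hierarchical_rw()` fits the model in JAGS (via `rjags`). Gibbs/slice
sampling handles this conjugate-ish Beta/Gamma hierarchy directly on the
constrained scale; beta nodes are truncated to $(0.001, 0.999)$ because
shape parameters below 1 (which the Gamma(1, 0.1) concentrations readily
produce) put infinite density at the unit-interval boundaries and strand
slice samplers there. Defaults are 4 chains × 1000 kept draws after 1000
burn-in iterations; per-chain RNG seeds derive from the user seed, so fits
are bit-reproducible. Every fit carries split-$\widehat{R}$ (computed from
half-chains) and effective sample sizes, and warns when
split-$\widehat{R} > 1.01$. Under the package's own simulation at the
study's scale (24 participants × 3 sessions × 12 pairs × 5 runs, 2 chains
× 500 draws) the posterior means of $a_{j,c}$ correlate with the
generating values at $r \approx 0.8$–$0.99$ across seeds; the acceptance
suite asserts $r \ge 0.7$.

## Value trajectories and the probe covariate

Day 2 choice analyses need, per probe trial, the learned-value difference
between the sated-associated and non-sated stimulus,
$w_{SA} - w_{NS}$. We compute terminal Day 1 values by plugging the
posterior-mean $\alpha$ of each pair into the closed form at that pair's
final presentation count (no further updating occurs on Day 2, which has
no feedback). Whether the original analysis evaluated this per posterior
draw or at a point estimate is not stated; the plug-in estimate is the
default because it is deterministic and the closed form is convex enough
that the two differ little in practice, and
`posterior_value_trajectories(method = "draws")` provides the per-draw
average as an option.

# Behavioral inference

All mixed models use `lme4` with participant random intercepts only,
matching the model formulas being mirrored, and single-term
likelihood-ratio tests on 1 df (linear models refitted by maximum
likelihood). Specifically:

* **Discrimination learning** — logistic model of odor-predictive choices
  on run number (1–5) against the intercept-only model.
* **Pleasantness change** — linear model of per-odor post-minus-pre
  pleasantness change (z-scored within participant across all sessions,
  odors and phases) on sated status; session-wise satiation index
  `SatIdx = PleasantChange(sated) − PleasantChange(non-sated)`, with
  single-moderator models for TMS condition, target group, session, and
  sated odor type.
* **Probe choices** — logistic model of post-meal sweet-vs-savory choices
  (1 = sated option) on TMS condition plus the covariates `ValueDiff`,
  `SatIdx`, and `BasePref`, against the covariates-only model. The Day 2
  contrast compares SS with SC sessions; the Day 1 contrast compares SS
  with CS (Day 2 TMS held at sham). With both target groups present, a
  TMS-by-group interaction model is also tested. `BasePref` is the
  proportion of sated-odor choices among pre-meal sweet-vs-savory trials
  only; odor-vs-air trials are excluded because the quantity serves as a
  sweet/savory preference baseline.

Model fit is summarized two ways: the correlation between per-participant
mean fitted probability and observed choice rate, and trial-level ROC AUC
computed from the rank (Mann–Whitney) statistic, pooled within each target
group × condition. Whether the original AUC summary pooled trials or
averaged per participant is not stated; pooling is implemented and both
views are recoverable from the per-trial table. Robustness uses
leave-one-subject-out refits of the probe model, and the per-participant
behavioral TMS effect is the difference in mean fitted sated-choice
probability between cTBS and sham conditions. Non-convergence of a mixed
model raises an error rather than passing silently; boundary (singular)
random-effect fits are tolerated because tiny intercept variances are
expected under the generator.

# Connectivity construction

The array-level operations consume already-aligned arrays and series
(registration is out of scope):

* **Multi-echo combination** follows the tSNR-weighted scheme: per voxel,
  weights proportional to tSNR × TE, normalized across echoes; voxels with
  no defined tSNR in any echo fall back to equal weights, with a message.
* **Framewise displacement** uses the Power formulation: summed absolute
  frame-to-frame translations plus rotations converted to arc length on a
  50 mm sphere (radius configurable); the first volume scores 0 and the
  session summary is the sum, excluding the first frame by definition.
* **Nuisance regression** z-scores the regressors, adds an intercept, and
  removes the OLS fit; rank-deficient designs raise an error naming the
  collinear columns.
* **Functional connectivity** is raw Pearson correlation (no Fisher
  transform, matching the quantity being mirrored; a z-transform option
  exists for the mixed-model contrasts) among the four experimental ROIs
  (4 × 4) and between each ROI and the AAL atlas regions. Regions with
  undefined signal are dropped and recorded; `common_fc_regions()`
  intersects kept regions across sessions so that every session's pattern
  vector lives in the same feature space, which the cVAE requires.
* **Network contrasts** summarize the labeled 4 × 4 matrix into
  within-network (each OFC seed with its own LPFC target), between-LPFC,
  and cross-network means, tested pairwise with participant-random-intercept
  models.

# Latent embedding of connectivity

Each of the four ROI pattern sets trains its own cVAE. The input is a
session's standardized connectivity vector (features z-scored to zero
mean and unit variance across all sessions, pooling conditions;
population-SD convention) concatenated with a one-hot participant code in
both encoder and decoder. The encoder is a 64-unit ReLU layer followed by
linear maps to the mean and log-variance of a 10-dimensional Gaussian
latent; training samples $z = \mu + \epsilon\,e^{0.5\log\sigma^2}$
(reparameterization trick) and minimizes the per-batch mean of the summed
squared reconstruction error plus the KL divergence from the standard
normal prior, with Adam at learning rate 3e-4 and seed 42 by default. The
network, back-propagation, and Adam are implemented directly in R matrix
arithmetic; training is full-batch and bit-reproducible given the
configuration seed. Log-variances are clamped to ±10 for numerical
safety, and a non-finite loss aborts with diagnostics rather than
continuing.

Conditioning on participant identity lets the decoder absorb stable
individual differences so the latent space can concentrate on
condition-related variation. The TMS statistic treats the null baseline
scan as a reference: every sham and cTBS session is embedded at its
posterior mean $\mu$ (deterministic mode; a sampled-z option exists, but
distances would then inherit sampling noise), and the Euclidean distance
to the participant's null embedding is averaged within condition (4 sham,
2 cTBS sessions when complete). The neural TMS effect is the cTBS mean
minus the sham mean, compared across participants with a two-sided paired
t-test. Participants lacking a null session or all sessions of a condition
are excluded with a log message; with the default missing-scan pattern
(5 sessions, 331 of 336 retained) 46 of 48 participants remain, matching
the analyzed cohort size.

Supporting diagnostics mirror the published checks: per-feature
Brown–Forsythe variance tests and Welch mean tests across conditions with
Benjamini–Hochberg FDR (the generator's standardized features should show
0 flagged features), reconstruction fidelity as the per-session Pearson
correlation between input and reconstruction compared between conditions,
an optional training mode that resamples sessions with weights inversely
proportional to each condition's session count (counterbalancing the 4:2
sham:cTBS imbalance), and a latent-dimension sweep over
{2, 4, 8, 12, 16, 32}.

# The synthetic cohort

The generator's defaults are the study conditions: 48 participants, three
sessions, 5 × 24 discrimination trials over 12 pairs, 30 pre-meal and 60
post-meal choice trials, seven connectivity sessions of 102 features with
5 missing cohort-wide. Where the data-generating process is not described
(it never is for noise), defaults were chosen once to look like plausible
human data and are stated here:

* Learning rates come from the model's own priors, so learning curves
  rise steeply (prior mean rate 0.8).
* Raw ratings sit on the −10..10 scale around a participant baseline of
  2 ± 1 with unit noise; the meal shifts the sated odor's post-meal rating
  by −2, a robust but not saturating devaluation.
* Probe choices follow the exact generative mirror of the fitted model:
  intercept −1.5, weights 3 (BasePref), 0.8 (SatIdx), 1.5 (ValueDiff),
  participant random intercepts with SD 0.5 on the log-odds scale, and a
  configurable additive cTBS effect (default 0.8 log-odds in the
  group/day combination where the study found effects). Under these
  settings trial-level AUCs land around 0.75, inside the 0.71–0.78 range
  reported for the real cohort.
* Connectivity sessions are a participant signature (feature SD 1) plus
  unit noise, with a constant 0.5-SD shift added to every feature of cTBS
  sessions by default. The default missing set removes one participant's
  null scan, both cTBS scans of another, and one sham scan from each of
  two more, reproducing the 331-session, 46-analyzable structure.

The generator emulates the *statistical* structure the analysis assumes —
not fMRI physics, realistic atlas covariance, hemodynamics, or
stimulus-level idiosyncrasies. Passing tests therefore demonstrate that
the pipeline is correct and calibrated under its own assumptions, not
that the scientific conclusions transfer to any particular real dataset.

# Numerical and testing choices

Tests and the acceptance script scale simulations to desk size while
keeping the study's structure: the recovery check uses 24 participants
with 2 chains × 500 draws; choice-model calibration uses 24-participant
cohorts with 18 trials per condition (100 null cohorts, 40 at the power
setting); the cVAE calibration/detection suites train 300-epoch models
(the full default is 500 epochs; at this problem size the 300-epoch
latent space already separates the injected shift, and the paired test's
null rejection rate is at its nominal level) on 100 null and 50 shifted
cohorts. The demonstration pipeline runs 6 participants with reduced
draws and epochs, twice, to assert manifest-level determinism. Degenerate
inputs are contracts, not afterthoughts: boundary learning rates,
constant features and regressors, missing sessions, single-class ROC
outcomes, and zero-variance paired differences all have defined,
tested behavior.

# Known limitations

* The learning model assumes the odor-predictive stimulus drives learning
  and that no value updating occurs on Day 2; alternative learning models
  (dual-rate, choice kernels) are out of scope.
* The cVAE is a small fixed architecture; no architecture search or GPU
  path is provided (unnecessary at 331 × 102).
* Real-data ingestion is limited to plain arrays/series and event tables;
  image registration and voxelwise target selection belong to upstream
  tooling.
* Reported p-values from the study itself depend on the real cohort and
  are not reproduced by the synthetic generator; the package's claims are
  about design arithmetic, closed forms, calibration, and power under its
  own generative assumptions.
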