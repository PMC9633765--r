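---
title: "Bayesian observer models of statistical pain-sequence learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian observer models of statistical pain-sequence learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painlearn)
```

## The problem

A participant receives a long stream of binary stimuli — low (L) or
high (H) intensity — and is occasionally asked to rate the probability
that the next stimulus will be high, given the current one. The stream is
generated by a two-state Markov chain whose transition matrix is
occasionally resampled ("jumps"), so both the marginal frequency of high
stimuli and the conditional transition probabilities drift over time.
`painlearn` provides the full modelling pipeline for this paradigm:
sequence generation with known ground truth, six candidate observer
models, per-subject model fitting, group-level model comparison,
behavioural accuracy statistics, and export of trial-wise model
quantities as first-level fMRI regressors.

## The generative process

Stimuli are drawn from a 2×2 transition matrix with free entries
p(H|L) and p(H|H) (rows are complementary). Chunk lengths between jumps
follow a geometric distribution with per-trial change probability
`p_jump = 0.014`, truncated to 6–199 trials by resampling; this is the
direct equivalent of flipping a change coin every trial while forbidding
very short and very long chunks, and avoids pathological rejection loops.
At each jump, both free probabilities are resampled uniformly from the
grid {0.15, 0.20, …, 0.85}, rejected until at least one of p(H|L), p(L|H)
moves by more than 0.2. Probes are scheduled with uniform gaps of 12–18
trials. Defaults produce 5 blocks × 300 trials; chunks continue across
block boundaries, and the first stimulus of a run is a fair coin (the
task description is silent on both points; these are the package's
declared conventions). The stationary frequency of high stimuli is
derivable from the matrix as

$$\pi_H = \frac{p(H|L)}{p(H|L) + 1 - p(H|H)},$$

which is also how rated frequencies are derived from conditional ratings
(see below).

With these parameters the truncated-geometric mean chunk length is
about 60 trials (the acceptance script reports the simulated value).
Shorter chunks would require either a larger `p_jump` or tighter
truncation; we deliberately keep the stated parameters rather than
matching any particular summary statistic.

## The six observer models

All models emit, at every trial `t`, the predictive probability that
trial `t+1` is high given the stimuli observed so far. This is the
quantity aligned with probe ratings and with imaging regressors.

* **random** — fixed reciprocal probabilities, `p(H) = 1 - p_l`, with
  `p_l` free. Uncertainty is fixed by assumption; the trace reports the
  flat-prior SD (1/√12) so that downstream code always receives a finite
  uncertainty column.
* **rw** — a Rescorla–Wagner delta rule on the value of "low":
  `V ← V + α(R − V)` with `R = 1` for low stimuli and `p(H) = 1 − V`.
  The start value `v0` defaults to 0.5 and is exposed as an optional
  parameter. The model has no posterior, so posterior SD and KL are
  absent from its trace.
* **fixed_frequency** — a Beta–Bernoulli learner with leaky integration:
  the stimulus `k` trials back receives weight `exp(-k/d)`, and stimuli
  beyond the last `w` trials receive weight zero; window and decay act
  simultaneously. The posterior is `Beta(N_H + 1, N_L + 1)` on the
  weighted counts and the prediction is the Laplace rule
  `(N_H + 1) / (N_H + N_L + 2)`.
* **fixed_transition** — the same leaky counting applied to successive
  stimulus pairs; the posterior is a product of independent Betas over
  θ(H|L) and θ(L|H), and the prediction reads the component conditioned
  on the current stimulus.
* **jump_frequency** — a change-point learner: the tracked frequency θ
  can be resampled from a flat prior with per-trial probability
  `p_jump`. Implemented as forward filtering of the equivalent hidden
  Markov model on a discretised grid: mix the posterior with the flat
  prior, multiply by the Bernoulli likelihood, renormalise. The
  prediction for the next trial integrates θ against the jump-mixed
  posterior, so a larger `p_jump` shrinks predictions toward 0.5.
* **jump_transition** — the same filter over the joint 2-D grid of
  (θ(H|L), θ(L|H)). A jump resamples both probabilities together, so the
  joint posterior is filtered as a whole and does not factorise; each
  trial's likelihood touches only the axis conditioned on the previous
  stimulus, and the first trial carries no transition evidence.

Posterior summaries per trial are the mean and SD of the posterior over
the probability of a high stimulus (for transition models, the
conditional component selected by the current stimulus) and the
Kullback–Leibler divergence between the posteriors at `t` and `t−1`:

$$D_{KL}(P \| Q) = \sum_x P(x) \log\frac{P(x)}{Q(x)},$$

evaluated on the shared discretised grid for every model, including the
fixed models whose posteriors have Beta closed forms — one code path for
all models, with the closed forms retained as test oracles. For the
product-form transition posterior the joint KL is the sum of the
per-axis KLs, which the implementation exploits.

## Numerical choices

* **Grids.** 100 uniform midpoints of (0, 1) for 1-D posteriors, 41×41
  for 2-D. Grid-refinement tests pin adequacy: predictions at the default
  resolution are within 1e-3 of a 10×-finer grid on volatile fixtures.
  The two jump filters are implemented in C++ (Rcpp) because they are the
  inner loop of model fitting; they were validated against a direct R
  implementation to ~1e-14.
* **KL mass floor.** Masses are floored at 1e-300 before logs, guarding
  floating-point underflow only; genuine disjoint support cannot arise
  because prior mixing keeps support full whenever `p_jump > 0`.
* **Limit behaviour.** At `p_jump = 1` the jump models predict 0.5
  everywhere (full reset to the flat prior). As `p_jump → 0` they reduce
  to the fixed models with a full window and no decay — but only on
  sequences without change-point evidence. On a volatile sequence, the
  likelihood ratio favouring a jump grows without bound after a true
  change, and eventually overwhelms any non-zero prior: at
  `p_jump = 1e-9` we observed divergences up to 0.2 in predictive
  probability on 1500-trial volatile runs, versus ~2e-5 on stationary
  runs. This is correct model behaviour, so the reduction tests use
  stationary single-chunk fixtures.
* **Degenerate inputs.** Posterior-mass underflow renormalises to flat
  with a warning; absorbing transition matrices (stationary frequency
  undefined) raise errors; rank-deficient rating regressions drop the
  offending column and flag the result.

## Fitting

Ratings are regressed on model predictions with a session covariate,

$$y_k \sim \beta_0 + \beta_1\, p_k(M_i, \theta_i) + \beta_2\, N_s + \epsilon,$$

and the fit is scored with
`BIC = n log(σ̂²) + k log(n)`, where `σ̂²` is the mean squared residual,
`n` the number of rated probes and `k` the number of free observer
parameters. Two interpretive decisions are worth recording: residuals are
squared (an unsquared residual mean can be negative, leaving the log
undefined), and `n` counts observations while `k` counts observer
parameters — the regression coefficients appear identically in every
model and are excluded from `k`, which preserves model rankings. The
session covariate enters as a number, not a factor. `σ̂²` is floored at
1e-9 so perfect fits keep a finite criterion.

Free parameters are optimised by multi-start bounded search: probability
parameters on a logit scale (`p_l`, `α` in (0, 1); `p_jump` in
[1e-4, 0.5]), decay on a log scale in [1, 1000], and the integer window
on a log-spaced grid from 1 to the sequence length, searched exhaustively
within each restart while decay is optimised by quasi-Newton descent from
the restart's random start. `fit_subject()` defaults to 100 restarts and
reports the across-restart mean of parameters and BIC (`mode = "mean"`,
the study's stated procedure); `mode = "best"` returns the best restart
and is what the recovery analyses use, since the mean over a
possibly multi-modal restart distribution blurs sharp recoveries. Tests
and the acceptance script use 2–6 restarts: the 1-parameter objectives
are smooth on the transformed scale and the window grid is exhaustive, so
few restarts already locate the optimum; the default stays at 100 for
fidelity to the stated procedure.

## Model comparison

Fixed-effects comparison ranks models by subject-averaged BIC. The
random-effects comparison treats each subject's model identity as drawn
from population frequencies with a Dirichlet prior (α₀ = 1 per model),
iterating the standard variational Dirichlet-multinomial update —
responsibilities proportional to `exp(log-evidence + ψ(α_k) − ψ(Σα))`,
Dirichlet counts updated from responsibilities — to a 1e-6 tolerance.
Log evidence defaults to `−BIC/2` (Laplace scaling; `−BIC` is available
as a sensitivity toggle). Exceedance probabilities are Monte Carlo
estimates from 10⁶ posterior Dirichlet draws; with two models they match
the regularised-incomplete-beta closed form, which the tests exploit.
The Bayes omnibus risk compares the variational free energy of the
random-effects model with the evidence of the equal-frequency null,
`BOR = 1/(1 + exp(F1 − F0))`, and protected exceedance is
`pEP = EP·(1 − BOR) + BOR/K`.

## What the synthetic data can and cannot show

The generator reproduces the task's stimulus statistics exactly (grid,
chunk-length law, change constraint, probe cadence), and synthetic
raters are ideal observers plus clipped Gaussian rating noise — matching
the Gaussian-residual assumption of the fitting regression. Real
participants additionally show rating biases, lapses, drifting
strategies and sub-second response dynamics, none of which are modelled.
Passing recovery tests therefore demonstrates that the pipeline is
correct and well-conditioned under its own assumptions, not that real
data will be as decisive.

One structural finding from the recovery harness deserves emphasis.
Because every candidate model receives free regression coefficients and
the complexity penalty counts only observer parameters, models are not
equally identifiable:

* Data from the **random** observer (a constant plus noise) are absorbed
  by β₀ for every candidate; flexible one-parameter models then gain
  ~1 BIC unit per subject by chasing noise with their prediction series,
  at no complexity cost relative to the random model. The random model
  therefore essentially never wins its own recovery under this scoring
  scheme, and which flexible model wins is noise-driven.
* The **fixed_frequency** model's window-plus-decay predictions are
  mimicked (r ≈ 0.99) by a Rescorla–Wagner learner with one fewer
  parameter, making that pair the second-hardest to separate.

The remaining models — including both change-point learners — recover
cleanly: with 10 synthetic subjects per generative model at rating noise
0.05, the generative model attains the top random-effects frequency and
the best averaged BIC.

## Behavioural statistics

Per-subject accuracy is the Pearson correlation between rated and
generative probabilities at probe trials, where the generative value is
the chunk's true matrix at the probe trial (not a smoothed or empirical
value). Rated frequencies are derived from the most recent rating of each
conditional type, carried forward, through the stationary formula —
exactly the stationary identity when both ratings come from the current
chunk, and deliberately stale for pairs straddling a jump. Group
inference is a one-sample t-test with Cohen's d = mean/SD, and the
frequency-versus-transition accuracy contrast is a two-sided z-test on
paired Fisher-transformed coefficients.

## Regressor export

`build_events()` emits BIDS-style events — `all`, `high` and `low`
condition rows with duration 0 — and attaches three parametric modulators
to the `all` rows: posterior mean probability of high pain, KL update and
posterior SD, computed from a trace run at group-mean fitted parameters
(`group_mean_params()`), which reduces parameter noise in the imaging
design. The KL modulator is the divergence between successive posteriors
over the tracked probability parameter; the volatility prior itself is a
fixed parameter, not a distribution, so there is no posterior "over jump
probability" to diverge. Modulators are mean-centred per session by
default (the downstream software's convention) and exported
un-orthogonalised; both behaviours are flags. Writing uses 17 significant
digits so event files round-trip numerically exactly.

## Problem sizes used by the test suite

Unit tests run on 100–1500-trial fixtures. The recovery analyses use 20
subjects with full-length (1500-trial, ~100-probe) sequences for
volatility-prior recovery, and 10 subjects × 600-trial sequences per
generative model for the six-way model recovery, at rating noise
0.05–0.1. These sizes were chosen once as representative desk-scale
analyses; the fitting defaults themselves are independent of them.

## Known limitations

* Volatility is a fixed prior: the jump models do not learn `p_jump`
  over time, and no hierarchical volatility model is provided.
* The rating model is homoscedastic clipped Gaussian; no lapse or bias
  terms.
* Group-level inference on parameters is a simple arithmetic mean across
  subjects; there is no hierarchical estimation.
* The BIC-based scoring inherits the identifiability limits described
  above; conclusions about the random and fixed_frequency models from
  this pipeline should be read with those limits in mind.
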