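---
title: "Methods: Q-learning analysis of the probabilistic selection task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Q-learning analysis of the probabilistic selection task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task and the generative model

The probabilistic selection task (PST) trains participants on three fixed
symbol pairs — A/B, C/D, E/F — with reward probabilities 0.8/0.2, 0.7/0.3 and
0.6/0.4 (within each pair the probabilities sum to one). Training comprises
`n_blocks = 6` blocks of 60 trials, exactly 20 presentations of each pair per
block, followed by a 60-trial feedback-free test phase over all 15 unordered
pairs (four presentations each; twelve of the pairs are novel combinations).

Choices are modelled by Q-learning with softmax choice. Each symbol carries an
expected value \(Q\), initialised at zero; after feedback \(r_t \in \{0, 1\}\)
on the chosen symbol,

\[ \delta_t = r_t - Q(c_t), \qquad Q(c_t) \leftarrow Q(c_t) + \alpha_{\mathrm{eff}}\,\delta_t, \]

where \(\alpha_{\mathrm{eff}} = \alpha\) in the single learning rate model,
and \(\alpha_{\mathrm{reward}}\) for \(\delta_t \ge 0\) versus
\(\alpha_{\mathrm{loss}}\) for \(\delta_t < 0\) in the dual model. Only the
chosen symbol's value updates (no counterfactual updating). The probability of
choosing the left of two options is the two-option softmax
\(p = 1/(1 + e^{-\beta (Q_L - Q_R)})\), with inverse temperature
\(\beta \ge 0\).

Two likelihood scopes are supported. Under `training`, only training choices
contribute. Under `training_plus_test` the log-density is additionally
incremented on test-phase choices, with Q-values frozen at their
end-of-training state (there is no feedback to learn from); parameters
estimated under this scope are conventionally reported primed
(\(\alpha'\), \(\beta'\)).

### Conventions and edge cases

* Ties (\(\delta_t = 0\)) use the reward learning rate. With rewards in
  \(\{0,1\}\) and zero initialisation, keying the rate on the sign of
  \(\delta\) coincides with keying it on the reward value.
* Feedback is an independent Bernoulli draw on the chosen symbol's
  probability. Because within-pair probabilities sum to one, marginal
  contingencies match a coupled implementation; the choice is documented
  here because published task descriptions rarely state it.
* Softmax evaluation uses the numerically stable logistic form
  (`-log1p(exp(-x))`), so extreme \(\beta\) values cannot overflow.
* "Counterbalanced" pair order is implemented as a seeded random permutation
  of pair order per block with exact alternation of left/right assignment per
  pair (sides balanced to within one trial). Symbols are abstract labels
  A–F; on-screen rendering and per-participant symbol randomisation are
  presentation-layer concerns.

## Hierarchical estimation

Fits are per experimental group, never pooled: group contrasts are computed
downstream from individual-level posterior means, and per-group fitting keeps
hierarchical shrinkage from diluting a genuine between-group difference.

Individual parameters use a non-centred latent-normal construction,

\[ z_{ip} \sim \mathcal N(0, 1), \qquad
\alpha_{ip} = \Phi(\mu_p + \sigma_p z_{ip}), \qquad
\beta_i = \beta_{\mathrm{cap}}\,\Phi(\mu_p + \sigma_p z_{ip}), \]

with \(\beta_{\mathrm{cap}} = 10\), hyper-priors \(\mu_p \sim \mathcal N(0,1)\)
and \(\sigma_p \sim \mathcal N^{+}(0, s_p)\) with \(s_p = 0.2\) for learning
rates and \(1\) for the inverse temperature. These are the standard priors for
hierarchical PST models in the hBayesDM tradition; the probit transform keeps
learning rates in \([0,1]\) and \(\beta\) in \([0,10]\) in every draw, and the
prior predictive covers those ranges essentially uniformly.

The package's sampler is an adaptive Metropolis-within-Gibbs scheme
implemented in C++: each participant's latent block \(z_i\) receives a joint
Gaussian random-walk proposal, and each hyper-parameter (\(\mu_p\), and
\(\log \sigma_p\) with the Jacobian term) a scalar random walk. Proposal
scales adapt by Robbins–Monro (targets 0.3 for blocks, 0.44 for scalars,
step size \(t^{-0.6}\)) during warm-up only, so the post-warm-up chain is a
valid fixed-kernel MCMC. All randomness flows through R's RNG: a fit is
byte-reproducible given `mcmc_config(seed = )`, with chain \(c\) seeded
`seed + c - 1`.

Default desk-scale budgets are 4 chains with 600 warm-up and 1500 kept
iterations — a 60-participant, 360-trial fit runs in about a minute —
and all budgets are plain configuration for users who want
publication-scale runs (e.g. 4 × 4000 + 20000).

### Diagnostics and gating

`diagnose()` computes rank-normalised split-chain R-hat (maximum of the bulk
and folded statistics) and bulk ESS (Geyer initial monotone positive sequence
on the rank-normalised split chains) for every hyper-parameter and every
individual-level parameter. `exclude_unconverged()` drops individuals with
split R-hat \(\ge 1.1\) or bulk ESS \(< 100\) on any parameter — the
thresholds standard in this literature — and logs them.

## Model comparison

`compute_loo()` implements PSIS-LOO: per-trial importance ratios
\(1/p(y_i\mid\theta_s)\) are tail-smoothed by a generalised Pareto fit
(Zhang–Stephens quasi-Bayesian estimator, with the usual small-tail shrinkage
of \(\hat k\) towards 0.5) over the largest \(\min(0.2S, 3\sqrt S)\) weights,
truncated at the raw maximum. `LOOIC = -2\,\mathrm{ELPD}` holds identically by
construction and is still asserted on every comparison. The leave-one-out unit
is the individual trial, matching the pointwise log-likelihood draws the
sampler stores (the unit is a genuine modelling choice; participant-level LOO
would require grouped importance ratios and is out of scope). Points with
\(\hat k > 0.7\) are reported, not refit. The implementation is validated in
the test suite against exact leave-one-out (refitting \(n\) times) on a
conjugate normal toy model.

## Group inference

Individual-level posterior means are related to group membership or
transdiagnostic factor scores by Bayesian GLMs — gamma family with log link
for the positively-skewed learning rates (effects are then also reported as
multipliers, the per-draw exponential of the coefficient), gaussian with
identity link for inverse temperatures — adjusted for age, gender and digit
span (plus distancing status when the predictor is a factor score).
Coefficient priors are autoscaled weakly-informative normals
(scale \(2.5\,s_y/s_x\) on the link scale), the gamma shape has an
exponential(1) prior, and sampling is component-wise adaptive MH. Reported
intervals are highest-density intervals (empirical shortest interval) at 95%
and 99%.

Two-stage inference (point estimates into a GLM) follows standard practice
for this design but understates posterior uncertainty in the individual
parameters; it is the documented trade-off, not an oversight. The multiplier
is summarised as the mean of \(e^{\mathrm{coef}}\) over draws;
\(e^{\overline{\mathrm{coef}}}\) is also exported since the two differ
slightly by Jensen's inequality.

The increasing-blocks analysis refits the dual model per group to blocks
\(1..k\) for \(k = 1..6\) and re-runs the group GLMs at each \(k\). All
earlier trials are always included because the start of training is the only
point at which all Q-values can be assumed zero; estimates at larger \(k\)
are therefore cumulative, not per-block.

## Behavioural statistics

Training accuracy is the proportion of choices of the better symbol per pair
per block, plus a trailing-window curve (window = 20 presentations, one
block's worth). Test accuracy is tabulated by pair category — training,
chooseA, avoidB, novel — where "correct" means the symbol with the higher
training reward probability; a full 60-trial test phase contributes exactly
12/16/16/16 trials to the four categories.

The group test is a van-Elteren-style stratified Kruskal–Wallis: within-block
rank sums are centred, weighted by \(1/(n_s+1)\), combined and squared over
the tie-corrected variance, giving a \(\chi^2_1\) statistic that reduces
exactly to the ordinary tie-corrected Kruskal–Wallis statistic in a single
stratum. The omnibus ("multivariate") variant sums the per-outcome statistics
and draws its p-value from a within-stratum label-permutation null. The exact
construction of the multivariate stratified test used in the applied
literature is not standardised; both modes here are exactly defined, and
neither claims to replicate any particular published \(\chi^2\) value.
Holm–Bonferroni adjustment delegates to `stats::p.adjust`.

## Synthetic cohorts

`generate_cohort()` emulates the structure of a large online two-arm study:
995 participants by default, half randomised (exactly) to the distanced arm.
Individual parameters are drawn from the same latent-normal construction the
fitting model assumes, with control-group means corresponding to
\(\alpha_{\mathrm{reward}} = 0.30\), \(\alpha_{\mathrm{loss}} = 0.15\),
\(\beta = 2.0\), latent SDs 0.25/0.25/0.30, and group effects stated on the
natural scale: a 1.2-fold loss-learning-rate multiplier and a +0.2 shift in
\(\beta\) (reward learning rate unshifted). These defaults encode the kind of
distancing effect the pipeline is designed to detect; effect sizes, noise
levels and sample sizes are configuration, not constants.

Also emitted: age (truncated normal, mean 45, SD 15, 18–80), binary gender,
digit span (rounded normal, mean 7, SD 1.3, plus a 0.5% chance of a zero
span), affect ratings after every training trial (cycling
happy/confident/engaged; intercept 70, slope −1.0 per block, +0.425
group-by-block interaction, noise SD 10, clamped to 0–100), a 209-item
questionnaire battery generated from a sparse 3-factor model (30 informative
items, ordinal 0–4 by thresholding), catch-question outcomes (two standard,
error rate 0.008 each; two harder, 0.14 each) and
neurological-disorder/low-English flags. `apply_exclusions()` implements the
corresponding filters (any standard catch wrong; both harder wrong; zero
span; either flag) and is idempotent.

What the generator deliberately does *not* emulate: reaction times, real
questionnaire item content, recruitment batch structure, non-stationary
learning rates within a participant, lapses or choice perseveration. Passing
tests on these cohorts therefore demonstrates internal consistency of the
pipeline (simulate → fit → infer recovers what was planted), not that real
participants obey the model.

## Factor scoring

The battery-reduction step is a multi-target lasso: `fit_subset_path()` fits
a multi-response gaussian lasso (glmnet `mgaussian`) of the three factor
scores on the item ratings. The penalty is a group penalty on each item's
coefficient triple, so the three factors share a single selected question
subset — per-target lassos would not produce a shared support. Predictive
accuracy is 5-fold cross-validated R² per factor (R² against the overall
target variance, so the empty model scores ≤ 0);
`select_operating_point()` returns the sparsest subset with CV R² ≥ 0.9 on
all three factors and errors explicitly when none qualifies. Items are
standardised internally by glmnet and coefficients reported on the original
rating scale; penalised coefficients are used for prediction as-is (no
debiasing refit). The original 209-item reference dataset is not packaged;
the module is validated on planted-factor synthetic batteries, where the
selected operating point recovers the informative items and held-out score
correlations exceed 0.9.

## Problem sizes used in the shipped checks

The acceptance script and test suite run the full pipeline at desk scale,
chosen so the whole suite completes in minutes on one core: parameter
recovery on 60 participants per group with the full 360 training trials
(4 chains × 600 + 1500); model selection on 10 cohorts of 10 participants
with a strongly dual generative regime
(\(\alpha_{\mathrm{reward}} = 0.4, \alpha_{\mathrm{loss}} = 0.1\)); group
-effect recovery on 150 participants per group at a reduced 2-chain budget;
factor scoring on 450 training plus 150 held-out respondents. These sizes
are the package's documented reference configuration, and every one of them
is a function argument.

## Known limitations

* Random-walk MCMC mixes more slowly than gradient-based samplers; the
  defaults compensate with cheap iterations, but hyper-SD parameters are the
  slowest-mixing quantities and deserve a glance at `diagnose()` output in
  any new application.
* Two-stage group inference understates individual-parameter uncertainty.
* The likelihood assumes parameters fixed within the fitted trial range; the
  increasing-blocks analysis probes, but does not model, within-task drift.
* No lapse, perseveration or forgetting parameters; zero initial Q-values
  are assumed known.
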