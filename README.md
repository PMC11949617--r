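# pstlearn

Reinforcement-learning analysis of two-group **probabilistic selection task
(PST)** experiments — the design used to ask how an intervention (for
example, a cognitive-distancing instruction delivered during training)
changes the computations underlying reward learning. The package is aimed at
computational-psychiatry researchers who want the entire pipeline — task
schedules, Q-learning likelihoods, hierarchical Bayesian fits, model
comparison, group-level GLMs, behavioural statistics and questionnaire
factor scoring — as tested, seeded, reusable R functions.

## The model

Participants choose repeatedly between symbol pairs A/B, C/D, E/F with
reward probabilities 0.8/0.2, 0.7/0.3, 0.6/0.4 (six 60-trial training
blocks, twenty of each pair per block), then face all fifteen pair
combinations in a 60-trial feedback-free test phase. Choices are modelled by
Q-learning with softmax choice:

$$\delta_t = r_t - Q(c_t), \qquad Q(c_t) \leftarrow Q(c_t) + \alpha_{\text{eff}}\,\delta_t, \qquad P(\text{left}) = \frac{1}{1 + e^{-\beta (Q_L - Q_R)}}$$

with a single learning rate α, or separate α_reward (δ ≥ 0) and α_loss
(δ < 0). The likelihood can additionally include test-phase choices with
Q-values frozen at end of training ("training-plus-test"; primed
parameters). Models are fit hierarchically per experimental group —
latent-normal individual parameters, probit-transformed to α ∈ [0, 1] and
β ∈ [0, 10] — by an adaptive Metropolis-within-Gibbs sampler (C++), with
rank-normalised split-R̂ / bulk-ESS diagnostics, PSIS-LOO model comparison,
and Bayesian gamma-log / gaussian GLMs relating individual posterior means
to group membership or transdiagnostic symptom scores. A synthetic-cohort
generator produces complete study-shaped datasets (trials, covariates,
affect ratings, a 209-item questionnaire battery from a planted 3-factor
model, catch questions) with known ground truth.

## Worked example

```r
library(pstlearn)

# a synthetic two-arm cohort: 1.2x loss learning rate, +0.2 inverse
# temperature in the distanced arm
co <- generate_cohort(cohort_config(n_participants = 120, seed = 11))

# hierarchical dual-learning-rate fit of one arm
fit <- fit_group(co$trials[co$trials$group == "control", ],
                 model_spec("dual", "training"),
                 mcmc_config(chains = 4, warmup = 600, iter = 1500, seed = 2))
print(fit)
#> Hierarchical Q-learning fit (dual learning rate, scope training)
#>   group: control | 60 participants | 4 chains x 1500 draws
#>   alpha_reward  latent mu = -0.569, sigma = 0.275
#>   alpha_loss    latent mu = -1.084, sigma = 0.384
#>   beta          latent mu = -0.881, sigma = 0.327

diagnose(fit)
#> MCMC diagnostics (rank-normalised split chains)
#>   hyper-parameters: max R-hat 1.102, min bulk ESS 40
#>   individuals:      max R-hat 1.040, min bulk ESS 96
```

The latent hyper-means sit near their generating values (qnorm(0.30) ≈
−0.52 for α_reward, qnorm(0.15) ≈ −1.04 for α_loss, qnorm(0.20) ≈ −0.84 for
β): the fit recovers the group that generated it. The diagnostics also show
why convergence gating exists — one individual's worst parameter lands just
under the bulk-ESS threshold of 100 at this desk-scale budget, and
`exclude_unconverged()` would drop (and log) exactly that participant.
Fitting both arms, gating on convergence, and passing the individual
posterior means to `fit_parameter_glm(..., family = "gamma-log")` yields the
group contrast as a multiplier with 95%/99% HDIs; `compare_models()` on dual
vs single fits reports the ELPD difference and LOOIC;
`training_accuracy()` / `stratified_kruskal_wallis()` give the model-free
contrasts; and `fit_subset_path()` / `select_operating_point()` /
`predict_scores()` reduce a 209-item battery to a sparse question subset
that predicts all three symptom dimensions with cross-validated R² ≥ 0.9.

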