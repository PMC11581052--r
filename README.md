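# aifbandit

Computational modelling of three-armed bandit behaviour for individual-
differences research. The package is aimed at computational-psychiatry
style analyses in which a cohort of participants plays a probabilistic
bandit (20 blocks x 16 trials; win probabilities fixed within a block,
changing between blocks), a generative model is fitted to every choice
sequence, and the fitted parameters carry the group-level questions —
for example whether clinical groups differ in how fast they learn from
losses or how quickly they forget.

## The model

The core agent is a single-step active inference model. Beliefs about
each option's outcome contingencies are Dirichlet pseudo-counts `a`
(columns normalise to the likelihood `A`); five parameters govern the
dynamics:

- `beta0` — initial decision noise (softmax precision `gamma = 1/beta`),
  which then *evolves*: the policy-belief change score
  `G_error = (pi_post - pi_pre) . (-G)` scales noise down after wins and
  up after surprising losses (random exploration);
- `eta_win`, `eta_loss` — concentration increments after wins and losses
  (learning);
- `omega` — per-trial decay of accumulated evidence toward the prior
  (forgetting / recency bias);
- `rho_p` — pessimism: the prior loss probability of untried actions,
  which suppresses directed exploration.

Options are valued by an expected free energy
`G = -(win utility) * A_win - (Dirichlet information gain)`, so
under-sampled arms earn an exploration bonus, and actions are drawn from
`softmax(-G / beta)`. Rescorla-Wagner comparison models and lesioned
variants share the same interface. Around the agent sit MAP fitting with
Laplace model evidence, random-effects Bayesian model selection
(protected exceedance probabilities with a Bayes omnibus risk),
model-free metrics (win-stay / lose-shift, iterative Grubbs outlier
screening, reaction-time coupling with model-derived confidence),
synthetic cohort generation with planted group effects, and frequentist
(sum-coded GLM + estimated marginal means) plus empirical-Bayes
(precision-weighted GLM with Bayesian model reduction) group inference.

See the methods vignette (`vignettes/aifbandit-methods.Rmd`) for the
full algebra and every design decision.

## A worked example

Simulate one agent at known parameters, then invert its choices:

```r
library(aifbandit)

sched <- make_schedule(seed = 7)                    # 20 blocks x 16 trials
truth <- list(beta0 = 0.4, eta_win = 0.6, eta_loss = 0.45,
              omega = 0.3, rho_p = 0.57)
sim <- simulate_agent(truth, sched, seed = 11)
fit <- fit_map(sim$trials)
print(fit)
#> MAP fit of 'aif_full' on 320 trials
#>               beta0 eta_win eta_loss   omega   rho_p
#> native       0.4043  0.5145   0.4126  0.2941  0.5659
#> transformed -0.9056  0.0582  -0.3534 -0.8756 -0.5693
#> log evidence -222.87 | loglik -214.05 | accuracy 0.688 | mean P(choice) 0.602
```

Every generative value is recovered close to truth from 320 choices; the
fitted model predicts 68.8% of this agent's choices (chance = 33%) and
assigns them an average probability of 0.60. `model_free_summary()`
gives the matching model-free picture (here 183 wins, win-stay 0.69,
lose-shift 0.91), and `trial_diagnostics()` exposes the trial-wise
confidence streams used in reaction-time analyses.

Cohort-scale work goes through `preset_designs()` / `sample_cohort()`
(synthetic groups with planted parameter differences), `fit_cohort()`,
`group_parameter_tests()` (GLM + EMM contrasts) and
`peb_parameter_tests()` (Bayesian model reduction), with
`evidence_matrix()` + `rfx_bms()` for model comparison.

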