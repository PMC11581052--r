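---
title: "Modelling three-armed bandit behaviour with aifbandit: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling three-armed bandit behaviour with aifbandit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The task and the modelling problem

The three-armed bandit task presents, on every trial, three options with
fixed but unknown win probabilities. Probabilities are stable within a
block and change between blocks (20 blocks of 16 trials by default), so a
player must repeatedly balance exploration (finding the currently best
arm) against exploitation (milking it). Choice sequences from this task
are widely used to estimate individual differences in learning, forgetting
and decision noise — quantities that differentiate clinical populations
even when raw performance measures do not.

`aifbandit` implements this analysis chain end to end: a generative agent
and its comparison models, single-subject model inversion, random-effects
model selection, model-free behavioural metrics, synthetic cohorts with
known ground truth, and group-level inference.

# The winning generative model

The agent maintains a 2 x 3 concentration matrix $a$ of Dirichlet-style
pseudo-counts (rows: win/loss; columns: options). Column-normalising $a$
gives the action-outcome likelihood $A$. Five parameters govern the
dynamics:

| parameter | space | role |
|---|---|---|
| $\beta_0$ | $(0,\infty)$, log-fitted | initial decision noise; precision $\gamma = 1/\beta$ |
| $\eta_{win}$ | $(0,1)$, logit-fitted | concentration increment after each win |
| $\eta_{loss}$ | $(0,1)$, logit-fitted | concentration increment after each loss |
| $\omega$ | $(0,1)$, logit-fitted | per-trial decay of accumulated evidence toward the prior (recency bias) |
| $\rho_p$ | $(0,1)$, log-fitted | pessimism: prior loss probability of every untried action |

**Valuation.** Each option $j$ is scored by an expected free energy

$$G_j \;=\; -\,c_{win}\,A_{win,j} \;-\; \tfrac{1}{2}\sum_o A_{oj}
\Big(\frac{1}{a_{oj}} - \frac{1}{\sum_{o'} a_{o'j}}\Big),$$

the sum of a pragmatic term (expected reward utility, with a win worth
$c_{win}$ and a loss worth 0) and a novelty bonus — the Dirichlet expected
information gain about that option's outcome probabilities, which decays
as concentration mass accumulates. Lower $G$ is better; the bonus makes
under-sampled options attractive (directed exploration), and higher
$\rho_p$ suppresses it indirectly by lowering the pragmatic appeal of
untried arms.

**Action selection.** Choices are sampled from
$\pi = \sigma(-G/\beta)$, a softmax with precision $\gamma = 1/\beta$
(computed with max-subtraction).

**Noise dynamics.** After observing outcome $o$, the pre-outcome policy
distribution is reweighted by each action's outcome surprise
$F_j = -\ln A_{o j}$ to give post-outcome policy beliefs
$\pi^{post} = \sigma(-\gamma G - F)$. The signed policy-belief change

$$G_{error} = (\pi^{post} - \pi)\cdot(-G)$$

is positive when the outcome pushes beliefs toward valuable actions
(wins) and negative when it pushes them away (surprising losses), and
drives the noise multiplicatively, $\beta \leftarrow
\max(\beta_{floor},\, \beta\, e^{-G_{error}})$. Noise therefore rises
after surprising losses and falls after wins — random exploration that
waxes and wanes with performance. $F$ at the chosen action and
$G_{error}$ are exposed per trial as diagnostics, alongside the policy
entropy (choice uncertainty, in nats) and a signed belief update
(change in the probability assigned to the previously preferred action).

**Learning and forgetting.** The accumulated evidence first decays toward
the prior, $a \leftarrow a_0 + (1-\omega)(a - a_0)$, then the observed
cell is incremented by the outcome's learning rate. $\omega = 0$ leaves
history untouched; $\omega = 1$ keeps only the prior plus the current
trial's increment. Decay-before-increment (rather than after) is what
makes the $\omega = 1$ boundary behave as a pure one-trial memory, and is
the order implemented in both engines. Beliefs and noise reset fully at
block boundaries, because the contingencies they describe do.

## Fixed constants and why they matter

Four constants complete the algebra ([`aif_control()`]); their defaults
were set during model development on identifiability grounds and are not
fitted:

- **Win utility $c_{win} = 4$.** The utility scale and the $\beta_0$ range
  jointly set how value-sensitive behaviour is. With a weak utility scale
  a change of learning rate can be mimicked almost exactly by a change of
  softmax temperature — a structural ridge we mapped explicitly
  (conditional likelihood profiles in $\eta$ are sharply peaked while
  joint profiles were nearly flat along an $(\eta, \beta_0)$ direction).
  A stronger utility scale keeps even noisy agents value-driven and
  breaks part of that ridge.
- **Prior concentration mass 0.25 per column.** With unit prior mass,
  beliefs stay prior-dominated across a 16-trial block and learning rates
  barely reach behaviour; a quarter-unit prior makes beliefs
  evidence-dominated within a block, so the speed of saturation — the
  learning rate's fingerprint — is expressed.
- **Multiplicative noise update.** An additive $\beta$ step lets the
  noise trajectory saturate in a way that absorbs $\beta_0$; the
  multiplicative form keeps $\beta_0$ a pure scale factor of the whole
  trajectory and hence identifiable.
- **Floors.** $\beta$ is floored at $10^{-3}$ (prevents divergence of
  $\gamma$); action probabilities are floored at $10^{-10}$ inside the
  log-likelihood (numerical safety only — it never binds at fitted
  parameters).

The default block schedule draws each block's probability triple from a
menu of four (0.9/0.6/0.3, 0.8/0.5/0.2, 0.7/0.4/0.1, 0.6/0.35/0.15,
option order permuted). Heterogeneous blocks matter for the same
structural reason as the utility scale: if every block repeats one
triple, all blocks are statistically identical and the learning-rate /
temperature mimicry is near-exact; blocks that saturate at different
speeds break it. A single-triple schedule remains one `prob_menu`
argument away.

## Comparison models

The registry also provides a no-forgetting variant (`aif_no_forget`), a
no-forgetting static-noise variant (`aif_basic`), and three
Rescorla-Wagner models (`rw_single`, `rw_dual`, `rw_dual_rs`) with
$Q \leftarrow Q + \eta(r - Q)$, static softmax, and optional separate
rates and reward sensitivity. Nesting is exact and tested: the full model
with $\omega = 0$ and a frozen noise trajectory reproduces `aif_basic`
likelihoods to $10^{-10}$, and `rw_dual` with equal rates reproduces
`rw_single`.

# Model inversion

`fit_map()` maximises log-likelihood plus log-prior in transformed space
(logit for rates and forgetting, log for noise, pessimism and reward
sensitivity). Priors default to Gaussians with mean 0 and variance 1/2,
except pessimism, whose log-space prior is centred on $\log 0.5$: a
mean-0 log-space prior would place the prior loss probability at 1,
outside the parameter's domain. Log-space proposals with $\rho_p \ge 1$
are rejected inside the likelihood with a large penalty, preserving the
log transform.

The optimiser is multi-start Nelder-Mead: a pool of seeded,
over-dispersed candidate starts (twice the prior SD) is screened by the
objective, the best four are run to convergence, and the incumbent gets
one restart to escape collapsed simplexes. This matters: single prior-mean
starts missed sharp optima of low-noise agents by tens of nats in
development. The covariance is the inverse of the negative Hessian
(central finite differences, step $10^{-4}$; eigenvalues floored at
$10^{-8}$, with a flag when flooring was needed), and the log evidence is
the Laplace approximation
$\log p(y) \approx \log p(y,\theta^*) + \tfrac{d}{2}\log 2\pi +
\tfrac{1}{2}\log|\Sigma|$, validated in the test suite against direct
grid integration on a two-parameter slice (within one nat).

`recovery_study()` wraps the simulate-then-refit loop: generative
parameters from a broad sampler (rates and probabilities uniform on the
central 90% of (0,1), noise log-uniform on [0.1, 3]), one randomised
schedule per agent, correlations reported per parameter in transformed
space. A broad sampler is a deliberately harsher test than re-simulating
from fitted participants: it includes near-total forgetting and
near-random choice regimes in which learning rates are weakly expressed
in behaviour, so learning-rate correlations sit below the other three
parameters. Failed fits are excluded and counted, never silently dropped.

# Random-effects model selection

`rfx_bms()` treats the model identity as a random effect: variational
updates of Dirichlet weights over model frequencies, exceedance
probabilities by Monte-Carlo sampling of the Dirichlet posterior (default
$10^6$ draws, seeded), and a Bayes omnibus risk (BOR) from the free-energy
comparison between the random-effects model and the equal-frequency null,
$BOR = 1/(1 + e^{F_1 - F_0})$. Protected exceedance probabilities are
$pxp = xp\,(1 - BOR) + BOR/K$. Identical evidence columns give $xp = 1/K$
and a BOR near 1, pinning $pxp$ at $1/K$ — the symmetry test in the
suite.

# Behavioural metrics

`model_free_summary()` computes total wins, mean reaction time, win-stay
and lose-shift proportions. Stay/shift pairs are only counted within a
block: contingencies reset between blocks, so a boundary-straddling pair
would conflate learning contexts. Degenerate histories (no win with a
successor) report missing values rather than zeros.

`grubbs_iterative()` screens outliers: the most extreme value is tested
against the two-sided critical value
$G_{crit} = \frac{n-1}{\sqrt n}\sqrt{t^2/(n - 2 + t^2)}$ with
$t = t_{\alpha/(2n),\,n-2}$, removed while significant ($\alpha = 0.01$
by default), applied per measure.

`rt_coupling()` correlates reaction times with (i) same-trial choice
uncertainty and (ii) the previous trial's belief update, sign-flipped so
that confidence-reducing updates predict slowing; first trials of blocks
are excluded from the update pairing, zero-variance streams report
missing correlations. `coupling_group_tests()` runs the one-sample
t-tests against zero (with an explicit guard for degenerate zero-variance
samples: $t = 0, p = 1$ when centred on zero) and group GLMs on the
per-participant coefficients.

# Synthetic cohorts

`preset_designs("paper_like")` builds a three-group cohort (HC-like
n = 54, iAD-like n = 242, iSUD-like n = 147) whose native-space parameter
means and SDs match published group summaries for this task — including
elevated forgetting in both clinical-like groups and a lower loss
learning rate in the substance-use-like group — together with matching
sex ratios and age distributions. Because the generative population lives
in transformed space while the summaries are native-space, each (mean,
SD) pair is converted by quadrature moment matching: we find the
transformed-space Gaussian whose induced native moments (truncated to the
parameter's domain, which matters only for pessimism) match the targets
within 2%. `null_groups` equalises the groups, `strong_effects` doubles
the separations around the grand mean in transformed space, and
`recovery_broad` defers to the broad sampler.

Reaction times are generated as
$RT = 500 + 250\,H(t) + 100\,(-\Delta b(t-1)) + \varepsilon$, in
milliseconds, with $H$ the choice uncertainty, $\Delta b$ the previous
trial's signed belief update, $\varepsilon \sim N(0, 150^2)$, floored at
150 ms. The slopes were chosen once to plant positive, moderate
within-subject couplings (population mean correlations of roughly
0.1-0.4, the regime in which such couplings are typically observed);
they are design fields, not estimates.

What the generator does *not* emulate: real participants' lapses,
within-session drift, RT distributions' heavy right tails,
or any questionnaire-derived phenotype. Passing tests on these cohorts
therefore demonstrates that the pipeline is correct and well calibrated
under its own assumptions — not that the model fits human data. Because
human behaviour carries noise sources the generator deliberately omits,
fitted-model accuracies on synthetic cohorts run higher than one should
expect on real participants.

# Group inference

The frequentist path (`fit_group_glm()`) is OLS with a sum-coded group
factor, mean-centred age and sex coded ±1/2 (keeping the intercept at the
sample-typical participant), the omnibus group F from full-vs-reduced
model comparison, partial $\eta^2$ from the sums of squares, and
estimated-marginal-mean contrasts (unadjusted) via the emmeans package.
No correction is applied across the five parameter-wise models; outputs
say so.

The Bayesian path (`peb_bayes_glm()`) is a parametric-empirical-Bayes
style second level: first-level posterior means regressed on the design,
each participant weighted by first-level posterior precision plus a
group-level residual variance estimated by evidence maximisation on the
full model. Reduced models that zero subsets of effects are scored by the
closed-form Gaussian log evidence — exhaustively for up to four effects,
greedy backward elimination beyond — and effects retained in the winning
model receive a posterior probability of deviating from zero (mass on
the sign of the posterior mean), banded at 0.75/0.95/0.99. This one-pass
scheme deliberately approximates the full iterative empirical-prior
machinery; the Monte-Carlo calibration tests (planted effects retained,
null effects zeroed, homoscedastic case matching weighted least squares)
define exactly what it is trusted to do. The per-coefficient prior
variance defaults to $10^4$ — effectively flat on the scale of parameter
effects — so point estimates coincide with weighted least squares while
model reduction still penalises free effects decisively.

# Numerical and scale choices

- Option indices are 1-based in every user-facing table and 0-based only
  inside the compiled filters.
- The compiled (Rcpp) filter is the production path; an R reference
  implementation of the identical dynamics (`init_beliefs()`,
  `observe_and_update()`, ...) is exported, and the suite asserts
  agreement between the two engines to $10^{-10}$.
- All randomness flows through explicit seeds; simulation, schedule
  generation and fitting draw sub-seeds from a single stream, so any
  cohort or study is reproducible from one integer.
- Test problem sizes: the recovery benchmark runs 200 agents at the full
  20 x 16 task; the planted-effect power check runs 20 replicates of the
  full 443-participant cohort at 10 blocks per participant, and the size
  check 25 replicates of 120 participants at 8 blocks — enough for the
  Monte-Carlo bounds asserted, while keeping the suite comfortably
  runnable on one CPU.

# Known limitations

- Policies are single-step: one action per policy, no planning depth —
  appropriate for a bandit, wrong for sequential tasks.
- The decision-noise update is a local, one-step revision, not a full
  variational precision scheme.
- Learning-rate recovery under the *broad* sampler is intrinsically
  weaker than for the other three parameters (the sampler visits regimes
  where rates barely reach behaviour); interpret individual learning-rate
  estimates from short tasks with corresponding caution.
- The PEB second level assumes Gaussian first-level posteriors summarised
  by mean and variance; heavy-tailed or multimodal posteriors are not
  represented.

# A minimal session

```{r, eval = FALSE}
library(aifbandit)

# simulate one agent and invert it
sched <- make_schedule(seed = 7)
truth <- list(beta0 = 0.4, eta_win = 0.6, eta_loss = 0.45,
              omega = 0.3, rho_p = 0.57)
sim <- simulate_agent(truth, sched, seed = 11)
fit <- fit_map(sim$trials)
print(fit)

# a small cohort through the whole pipeline
des <- preset_designs("paper_like")
des$groups$n <- c(10L, 12L, 11L)
coh <- sample_cohort(des, seed = 1)
tab <- fit_cohort(coh$trials)
dat <- merge(tab, coh$truth[, c("participant_id", "age", "sex")],
             by = "participant_id")
group_parameter_tests(dat, outcomes = c("omega_t", "eta_loss_t"))
```
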