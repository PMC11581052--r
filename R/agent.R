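# Active inference agent for the three-armed bandit: belief representation,
# expected free energy, policy selection, and the per-trial update rule.
#
# The agent tracks a 2 x 3 concentration matrix `a` of Dirichlet-style
# pseudo-counts (rows: win, loss; columns: options). Normalising each
# column yields the action-outcome likelihood A. Learning increments the
# observed (outcome, choice) cell by the corresponding learning rate;
# forgetting decays accumulated evidence toward the pessimistic prior a0;
# decision noise beta evolves with the signed policy-belief change after
# each outcome. Everything resets at block boundaries.

#' Control constants of the active inference agent
#'
#' @param pref_win Utility of a win in the pragmatic term of expected free
#'   energy (losses have utility 0). Sets the scale against which the
#'   decision-noise parameter is interpreted.
#' @param prior_mass Total concentration mass per option column in the
#'   initial matrix `a0`. The default (0.25) makes beliefs
#'   evidence-dominated within a 16-trial block, which the learning-rate
#'   parameters need in order to express themselves in behaviour.
#' @param beta_floor Lower bound on decision noise, preventing divergence
#'   of the precision gamma = 1/beta.
#' @param prob_floor Lower bound on per-trial action probabilities inside
#'   the log-likelihood (numerical safety only).
#' @param beta_step Gain on the decision-noise update (the policy-belief
#'   change score is multiplied by this before being applied to beta).
#' @param beta_update `"multiplicative"` (beta is scaled by
#'   `exp(-beta_step * G_error)`, keeping the initial noise a pure scale
#'   factor of the trajectory) or `"additive"`
#'   (`beta - beta_step * G_error`).
#' @return A list of constants, passed as `control` to likelihood,
#'   simulation and fitting functions.
#' @export
aif_control <- function(pref_win = 4, prior_mass = 0.25,
                        beta_floor = 1e-3, prob_floor = 1e-10,
                        beta_step = 1,
                        beta_update = c("multiplicative", "additive"),
                        novelty_weight = 1) {
  stopifnot(pref_win > 0, prior_mass > 0, beta_floor > 0, prob_floor > 0,
            beta_step >= 0, novelty_weight >= 0)
  beta_update <- match.arg(beta_update)
  list(pref_win = pref_win, prior_mass = prior_mass,
       beta_floor = beta_floor, prob_floor = prob_floor,
       beta_step = beta_step, beta_mult = beta_update == "multiplicative",
       novelty_weight = novelty_weight)
}

#' Parameters of the winning active inference model
#'
#' @param beta0 Initial decision noise (> 0); precision gamma = 1/beta0.
#' @param eta_win,eta_loss Learning rates for wins and losses in (0, 1).
#' @param omega Forgetting rate in `[0, 1)`: per-trial decay of accumulated
#'   evidence toward the prior (0 = none, 1 = full reset each trial).
#' @param rho_p Pessimism in (0, 1): prior loss probability assigned to
#'   every untried action.
#' @param beta_dynamic Should decision noise evolve with outcome surprise?
#' @return An `agent_parameters` object (named list).
#' @export
agent_parameters <- function(beta0, eta_win, eta_loss, omega, rho_p,
                             beta_dynamic = TRUE) {
  vals <- c(beta0 = beta0, eta_win = eta_win, eta_loss = eta_loss,
            omega = omega, rho_p = rho_p)
  if (any(!is.finite(vals))) stop("agent parameters must be finite")
  if (beta0 <= 0) stop("`beta0` must be > 0")
  for (nm in c("eta_win", "eta_loss", "omega")) {
    if (vals[[nm]] < 0 || vals[[nm]] > 1)
      stop(sprintf("`%s` must lie in [0, 1]", nm))
  }
  if (rho_p <= 0 || rho_p >= 1) stop("`rho_p` must lie in (0, 1)")
  structure(list(beta0 = beta0, eta_win = eta_win, eta_loss = eta_loss,
                 omega = omega, rho_p = rho_p,
                 beta_dynamic = isTRUE(beta_dynamic)),
            class = "agent_parameters")
}

#' Column-normalise a concentration matrix
#'
#' @param a A matrix with strictly positive entries (2 outcomes x options).
#' @return The likelihood matrix A with columns summing to 1.
#' @export
normalize_concentration <- function(a) {
  if (!is.matrix(a) || any(!is.finite(a)) || any(a <= 0))
    stop("`a` must be a matrix with strictly positive finite entries")
  sweep(a, 2, colSums(a), "/")
}

#' Initialise beliefs from agent parameters
#'
#' The prior concentration matrix `a0` gives every option a loss
#' probability of `rho_p` (win probability `1 - rho_p`) at total mass
#' `control$prior_mass` per column; decision noise starts at `beta0`; the
#' policy distribution is uniform before the first valuation. Block resets
#' re-apply this state.
#'
#' @param params An [agent_parameters()] object.
#' @param control Agent constants, see [aif_control()].
#' @return A `belief_state`: list with `a`, `a0`, `A`, `beta`, `pi`.
#' @export
init_beliefs <- function(params, control = aif_control()) {
  stopifnot(inherits(params, "agent_parameters"))
  a0 <- matrix(control$prior_mass *
                 c(1 - params$rho_p, params$rho_p), nrow = 2, ncol = 3)
  rownames(a0) <- c("win", "loss")
  colnames(a0) <- paste0("option", 1:3)
  structure(list(a = a0, a0 = a0, A = normalize_concentration(a0),
                 beta = params$beta0, pi = rep(1 / 3, 3)),
            class = "belief_state")
}

#' Expected free energy per option
#'
#' For each option j, `G[j] = -pref_win * A[win, j] - novelty[j]`, where
#' the novelty bonus is the Dirichlet expected information gain about that
#' option's outcome probabilities,
#' `0.5 * sum_o A[o, j] * (1 / a[o, j] - 1 / colsum_j)`, which shrinks as
#' concentration mass accumulates. Lower G marks the better option.
#'
#' @param state A `belief_state`.
#' @param control Agent constants, see [aif_control()].
#' @return Numeric length-3 vector of expected free energies.
#' @export
expected_free_energy <- function(state, control = aif_control()) {
  stopifnot(inherits(state, "belief_state"))
  a <- state$a
  cs <- colSums(a)
  A <- sweep(a, 2, cs, "/")
  novelty <- 0.5 * colSums(A * (1 / a - rep(1 / cs, each = 2)))
  unname(-control$pref_win * A["win", ] - control$novelty_weight * novelty)
}

#' Softmax policy distribution over options
#'
#' `pi = softmax(-G / beta)`: precision gamma = 1/beta scales the negative
#' expected free energies; computed with max-subtraction for overflow
#' safety. As beta grows the distribution approaches uniform.
#'
#' @param G Numeric vector of per-option expected free energies.
#' @param beta Decision noise (> 0).
#' @return A probability vector summing to 1.
#' @export
policy_distribution <- function(G, beta) {
  if (any(!is.finite(G))) stop("`G` must be finite")
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("`beta` must be a positive scalar")
  v <- -G / beta
  v <- v - max(v)
  e <- exp(v)
  e / sum(e)
}

#' Observe an outcome and update beliefs
#'
#' Noise dynamics: the pre-outcome policy distribution is reweighted by
#' each action's outcome surprise `F_j = -ln A(outcome | j)` to give the
#' post-outcome policy beliefs, and the signed policy-belief change score
#' `G_error = (pi_post - pi_pre) . (-G_pre)` drives the decision noise
#' (by default multiplicatively, `beta * exp(-beta_step * G_error)`,
#' floored at `control$beta_floor`), so beta rises after surprising
#' losses and falls after wins. Belief dynamics: forgetting first decays
#' the accumulated evidence toward `a0` by factor `omega` (so `omega = 1`
#' leaves `a0` plus only the current trial's increment), then learning
#' increments the (outcome, choice) cell of `a` by `eta_win` or
#' `eta_loss`.
#'
#' @param state A `belief_state`.
#' @param choice Option chosen, in 1..3.
#' @param outcome `"win"` or `"loss"`.
#' @param params An [agent_parameters()] object.
#' @param control Agent constants, see [aif_control()].
#' @return List with the updated `state` and a one-row `diagnostics` data
#'   frame (`G1..G3` pre-update, `entropy`, `F`, `G_error`,
#'   `belief_update`, `action_prob`, `beta` pre-update).
#' @export
observe_and_update <- function(state, choice, outcome, params,
                               control = aif_control()) {
  stopifnot(inherits(state, "belief_state"),
            inherits(params, "agent_parameters"))
  if (!(choice %in% 1:3)) stop("`choice` must be 1, 2 or 3")
  if (!(outcome %in% c("win", "loss")))
    stop('`outcome` must be "win" or "loss"')

  G_pre <- expected_free_energy(state, control)
  pi_pre <- policy_distribution(G_pre, state$beta)
  entropy <- -sum(pi_pre * log(pi_pre))
  A_pre <- normalize_concentration(state$a)
  Fvec <- -log(pmax(A_pre[outcome, ], 1e-16))
  Fsurprise <- Fvec[[choice]]

  # post-outcome policy beliefs: pre-outcome policies reweighted by how
  # well each action predicted the observed outcome
  v <- -G_pre / state$beta - Fvec
  v <- v - max(v)
  pi_post <- exp(v) / sum(exp(v))
  g_error <- sum((pi_post - pi_pre) * (-G_pre))
  jstar <- which.max(pi_pre)
  belief_update <- pi_post[[jstar]] - pi_pre[[jstar]]

  beta_pre <- state$beta
  if (params$beta_dynamic) {
    state$beta <- if (control$beta_mult)
      max(control$beta_floor, state$beta * exp(-control$beta_step * g_error))
    else max(control$beta_floor, state$beta - control$beta_step * g_error)
  }
  state$pi <- unname(pi_post)

  a <- state$a0 + (1 - params$omega) * (state$a - state$a0)
  row <- if (outcome == "win") "win" else "loss"
  eta <- if (outcome == "win") params$eta_win else params$eta_loss
  a[row, choice] <- a[row, choice] + eta
  state$a <- a
  state$A <- normalize_concentration(a)

  diagnostics <- data.frame(
    G1 = G_pre[1], G2 = G_pre[2], G3 = G_pre[3],
    entropy = entropy, F = Fsurprise, G_error = g_error,
    belief_update = belief_update, action_prob = pi_pre[choice],
    beta = beta_pre)
  list(state = state, diagnostics = diagnostics)
}
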