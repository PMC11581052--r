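# Model registry: the winning active inference model, its lesioned
# variants, and the Rescorla-Wagner comparison family. Each entry records
# the free parameters, their fitting transforms, and fixed configuration.

#' Registered computational models
#'
#' @return Named list of model descriptors. Available ids:
#'   \describe{
#'     \item{aif_full}{Active inference: dynamic decision noise, separate
#'       win/loss learning rates, forgetting, pessimism (5 parameters).}
#'     \item{aif_no_forget}{As `aif_full` with the forgetting rate fixed
#'       at 0 (4 parameters).}
#'     \item{aif_basic}{No forgetting and static decision noise
#'       (4 parameters).}
#'     \item{rw_single}{Rescorla-Wagner, one learning rate.}
#'     \item{rw_dual}{Rescorla-Wagner, separate win/loss learning rates.}
#'     \item{rw_dual_rs}{Dual rates plus a reward-sensitivity scale.}
#'   }
#' @export
model_registry <- function() {
  list(
    aif_full = list(
      id = "aif_full", family = "aif",
      label = "Active inference (dynamic noise + forgetting)",
      params = c("beta0", "eta_win", "eta_loss", "omega", "rho_p"),
      transform = c(beta0 = "log", eta_win = "logit", eta_loss = "logit",
                    omega = "logit", rho_p = "log"),
      fixed = list(), beta_dynamic = TRUE),
    aif_no_forget = list(
      id = "aif_no_forget", family = "aif",
      label = "Active inference, no forgetting",
      params = c("beta0", "eta_win", "eta_loss", "rho_p"),
      transform = c(beta0 = "log", eta_win = "logit", eta_loss = "logit",
                    rho_p = "log"),
      fixed = list(omega = 0), beta_dynamic = TRUE),
    aif_basic = list(
      id = "aif_basic", family = "aif",
      label = "Active inference, no forgetting, static noise",
      params = c("beta0", "eta_win", "eta_loss", "rho_p"),
      transform = c(beta0 = "log", eta_win = "logit", eta_loss = "logit",
                    rho_p = "log"),
      fixed = list(omega = 0), beta_dynamic = FALSE),
    rw_single = list(
      id = "rw_single", family = "rw",
      label = "Rescorla-Wagner, single learning rate",
      params = c("beta0", "eta"),
      transform = c(beta0 = "log", eta = "logit"),
      fixed = list(rs = 1)),
    rw_dual = list(
      id = "rw_dual", family = "rw",
      label = "Rescorla-Wagner, dual learning rates",
      params = c("beta0", "eta_win", "eta_loss"),
      transform = c(beta0 = "log", eta_win = "logit", eta_loss = "logit"),
      fixed = list(rs = 1)),
    rw_dual_rs = list(
      id = "rw_dual_rs", family = "rw",
      label = "Rescorla-Wagner, dual rates + reward sensitivity",
      params = c("beta0", "eta_win", "eta_loss", "rs"),
      transform = c(beta0 = "log", eta_win = "logit", eta_loss = "logit",
                    rs = "log"),
      fixed = list()))
}

#' @rdname model_registry
#' @param model A model id string.
#' @export
model_info <- function(model) {
  reg <- model_registry()
  if (!model %in% names(reg))
    stop(sprintf("unknown model id '%s'; registered: %s", model,
                 paste(names(reg), collapse = ", ")))
  reg[[model]]
}

# Internal: full native parameter set (free + fixed) for a model family.
resolve_params <- function(model, params) {
  info <- model_info(model)
  p <- as.list(params)
  for (nm in names(info$fixed)) p[[nm]] <- info$fixed[[nm]]
  if (info$family == "rw" && "eta" %in% names(p)) {
    p$eta_win <- p$eta
    p$eta_loss <- p$eta
  }
  missing <- setdiff(
    if (info$family == "aif")
      c("beta0", "eta_win", "eta_loss", "omega", "rho_p")
    else c("beta0", "eta_win", "eta_loss", "rs"),
    names(p))
  if (length(missing))
    stop("missing parameters for ", model, ": ",
         paste(missing, collapse = ", "))
  p
}

# Internal: run the C++ filter for any registered model on encoded trials.
model_filter <- function(model, params, enc, control = aif_control()) {
  info <- model_info(model)
  p <- resolve_params(model, params)
  if (info$family == "aif") {
    aif_filter_cpp(enc$block, enc$choice, enc$outcome,
                   p$beta0, p$eta_win, p$eta_loss, p$omega, p$rho_p,
                   info$beta_dynamic, control$pref_win, control$prior_mass,
                   control$beta_floor, control$prob_floor,
                   control$beta_step, control$beta_mult,
                   control$novelty_weight)
  } else {
    rw_filter_cpp(enc$block, enc$choice, enc$outcome,
                  p$beta0, p$eta_win, p$eta_loss, p$rs, control$prob_floor)
  }
}

#' Log-likelihood of a choice sequence under a registered model
#'
#' Replays the model's belief dynamics conditioned on the recorded choices
#' and outcomes, accumulating the log-probability assigned to each emitted
#' choice. Beliefs reset at block boundaries.
#'
#' @param params Named numeric vector or list of native-space parameters
#'   (the model's free parameters; see [model_registry()]).
#' @param trials Trial data frame (see [validate_trials()]), ordered by
#'   (block, trial).
#' @param model Model id.
#' @param engine `"cpp"` (default) or `"r"`; the R engine replays the
#'   dynamics through [observe_and_update()] and is available for the
#'   active inference family only.
#' @param control Agent constants, see [aif_control()].
#' @return List with `loglik` and the per-trial `action_prob` stream.
#' @export
sequence_log_likelihood <- function(params, trials, model = "aif_full",
                                    engine = c("cpp", "r"),
                                    control = aif_control()) {
  engine <- match.arg(engine)
  enc <- encode_trials(trials)
  if (engine == "cpp") {
    out <- model_filter(model, params, enc, control)
    return(list(loglik = out$loglik, action_prob = out$action_prob))
  }
  info <- model_info(model)
  if (info$family != "aif")
    stop("engine = 'r' is implemented for the active inference family")
  p <- resolve_params(model, params)
  ap <- agent_parameters(p$beta0, p$eta_win, p$eta_loss, p$omega, p$rho_p,
                         beta_dynamic = info$beta_dynamic)
  state <- NULL
  cur <- NA
  n <- length(enc$block)
  probs <- numeric(n)
  for (t in seq_len(n)) {
    if (is.na(cur) || enc$block[t] != cur) {
      state <- init_beliefs(ap, control)
      cur <- enc$block[t]
    }
    res <- observe_and_update(state, enc$choice[t] + 1L,
                              if (enc$outcome[t] == 1L) "win" else "loss",
                              ap, control)
    probs[t] <- res$diagnostics$action_prob
    state <- res$state
  }
  list(loglik = sum(log(pmax(probs, control$prob_floor))),
       action_prob = probs)
}

#' Trial-wise model diagnostics from a replay
#'
#' Replays a fitted (or generative) model over recorded choices/outcomes
#' and returns per-trial diagnostics: expected free energies, policy
#' entropy (choice uncertainty, nats), outcome surprise `F`, policy-belief
#' change `G_error`, signed belief update, action probability, and the
#' decision-noise trajectory (active inference family).
#'
#' @inheritParams sequence_log_likelihood
#' @return Data frame aligned with `trials`, with attribute `"loglik"`.
#' @export
trial_diagnostics <- function(params, trials, model = "aif_full",
                              control = aif_control()) {
  enc <- encode_trials(trials)
  out <- model_filter(model, params, enc, control)
  info <- model_info(model)
  d <- data.frame(block = enc$block,
                  trial = enc$trials$trial,
                  action_prob = out$action_prob,
                  entropy = out$entropy)
  if (info$family == "aif") {
    d$F <- out$F
    d$G_error <- out$G_error
    d$belief_update <- out$belief_update
    d$beta <- out$beta
  }
  attr(d, "loglik") <- out$loglik
  attr(d, "pi") <- out$pi
  d
}

#' Simulate an agent on a block schedule
#'
#' Forward-samples choices from the model's policy distribution and
#' outcomes from the scheduled reward probabilities, resetting beliefs at
#' block boundaries. Deterministic given `seed`.
#'
#' @param params Named native-space parameters for `model`.
#' @param schedule A [make_schedule()] object.
#' @param seed Optional integer seed.
#' @param model Model id.
#' @param control Agent constants, see [aif_control()].
#' @return List with `trials` (block, trial, choice, outcome, rt_ms = NA)
#'   and `diagnostics` (per-trial streams as in [trial_diagnostics()]).
#' @export
simulate_agent <- function(params, schedule, seed = NULL,
                           model = "aif_full", control = aif_control()) {
  stopifnot(inherits(schedule, "block_schedule"))
  info <- model_info(model)
  p <- resolve_params(model, params)
  out <- with_seed(seed, {
    if (info$family == "aif") {
      aif_sim_cpp(schedule$probs, schedule$n_trials_per_block,
                  p$beta0, p$eta_win, p$eta_loss, p$omega, p$rho_p,
                  info$beta_dynamic, control$pref_win, control$prior_mass,
                  control$beta_floor, control$beta_step, control$beta_mult,
                  control$novelty_weight)
    } else {
      rw_sim_cpp(schedule$probs, schedule$n_trials_per_block,
                 p$beta0, p$eta_win, p$eta_loss, p$rs)
    }
  })
  trials <- data.frame(block = out$block, trial = out$trial,
                       choice = out$choice,
                       outcome = ifelse(out$outcome == 1L, "win", "loss"),
                       rt_ms = NA_real_)
  diagnostics <- data.frame(block = out$block, trial = out$trial,
                            action_prob = out$action_prob,
                            entropy = out$entropy)
  if (info$family == "aif") {
    diagnostics$F <- out$F
    diagnostics$G_error <- out$G_error
    diagnostics$belief_update <- out$belief_update
    diagnostics$beta <- out$beta
  }
  list(trials = trials, diagnostics = diagnostics)
}
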