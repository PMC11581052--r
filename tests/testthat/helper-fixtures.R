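# Shared fixtures: small schedules, mid-range agents, hand-built trial
# tables. Everything is generated in code at test time.

mid_params <- function(beta_dynamic = TRUE) {
  list(beta0 = 0.4, eta_win = 0.6, eta_loss = 0.45,
       omega = 0.3, rho_p = 0.57)
}

small_schedule <- function(n_blocks = 4, n_trials = 12, seed = 3) {
  make_schedule(n_blocks, n_trials, seed = seed)
}

sim_trials <- function(params = mid_params(), n_blocks = 4, n_trials = 12,
                       seed = 5, model = "aif_full") {
  simulate_agent(params, small_schedule(n_blocks, n_trials, seed = seed),
                 seed = seed + 1, model = model)$trials
}

# Hand-built trial table from vectors (single block by default).
make_trials <- function(choice, outcome, block = rep(1, length(choice)),
                        rt_ms = NULL) {
  df <- data.frame(block = block,
                   trial = stats::ave(block, block, FUN = seq_along),
                   choice = choice, outcome = outcome)
  if (!is.null(rt_ms)) df$rt_ms <- rt_ms
  df
}

random_aif_params <- function() {
  list(beta0 = exp(runif(1, log(0.15), log(2))),
       eta_win = runif(1, 0.1, 0.9), eta_loss = runif(1, 0.1, 0.9),
       omega = runif(1, 0.05, 0.8), rho_p = runif(1, 0.2, 0.8))
}
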