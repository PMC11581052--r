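# Belief dynamics of the active inference agent: priors, expected free
# energy, policy selection, the per-trial update rule, and the agreement
# between the R reference implementation and the compiled filter.

test_that("initial beliefs encode pessimism symmetrically across options", {
  p <- agent_parameters(0.4, 0.6, 0.45, 0.3, rho_p = 0.5)
  st <- init_beliefs(p)
  expect_equal(unname(st$A["loss", ]), rep(0.5, 3))
  expect_equal(st$pi, rep(1 / 3, 3))
  expect_equal(st$beta, 0.4)
  expect_equal(st$a, st$a0)

  st9 <- init_beliefs(agent_parameters(0.4, 0.6, 0.45, 0.3, rho_p = 0.9))
  expect_equal(unname(st9$A["loss", ]), rep(0.9, 3))
})

test_that("concentration normalisation is a column-stochastic map", {
  expect_equal(normalize_concentration(matrix(c(1, 1), 2, 1))[, 1],
               c(0.5, 0.5))
  expect_equal(normalize_concentration(matrix(c(3, 1), 2, 1))[, 1],
               c(0.75, 0.25))
  set.seed(1)
  a <- matrix(rexp(12) + 0.01, 2, 6)
  expect_lt(max(abs(colSums(normalize_concentration(a)) - 1)), 1e-12)
  expect_error(normalize_concentration(matrix(c(1, 0), 2, 1)), "positive")
})

test_that("expected free energy trades off reward and information gain", {
  p <- agent_parameters(0.4, 0.6, 0.45, 0.3, 0.5)
  st <- init_beliefs(p)
  G <- expected_free_energy(st)
  expect_equal(G[1], G[2])
  expect_equal(G[2], G[3])

  # same win probability, 10x the concentration mass: the sampled-less
  # option promises more information and gets the lower (better) G
  st$a <- cbind(c(1, 1), c(10, 10), c(1, 1))
  rownames(st$a) <- c("win", "loss")
  G <- expected_free_energy(st)
  expect_lt(G[1], G[2])
  expect_equal(G[1], G[3])

  # equal mass, win probabilities 0.8 vs 0.2: reward dominance
  st$a <- cbind(c(0.8, 0.2), c(0.2, 0.8), c(0.5, 0.5)) * 2
  rownames(st$a) <- c("win", "loss")
  G <- expected_free_energy(st)
  expect_lt(G[1], G[2])
})

test_that("the policy softmax matches its closed form and limits", {
  expect_equal(policy_distribution(c(2, 2, 2), 0.5), rep(1 / 3, 3))
  # beta -> infinity: uniform regardless of G
  expect_equal(policy_distribution(c(0, 5, -3), 1e9), rep(1 / 3, 3),
               tolerance = 1e-6)
  # hand-computed softmax oracle at gamma = 1
  expected <- exp(-c(0, 1, 2)) / sum(exp(-c(0, 1, 2)))
  expect_equal(policy_distribution(c(0, 1, 2), beta = 1), expected,
               tolerance = 1e-12)
  expect_error(policy_distribution(c(0, NA, 1), 1), "finite")
  expect_error(policy_distribution(c(0, 1, 2), 0), "positive")
})

test_that("the update rule honours its learning and forgetting limits", {
  ctl <- aif_control()
  # unit increment: eta_win = 1 adds one count to the observed cell
  p <- agent_parameters(0.4, 1, 0.5, 0, 0.5)
  st <- init_beliefs(p, ctl)
  st$a["win", 2] <- 1.0
  res <- observe_and_update(st, 2, "win", p, ctl)
  expect_equal(res$state$a["win", 2], 2.0)

  # no-learning limit: a untouched for any outcome
  p0 <- agent_parameters(0.4, 0, 0, 0, 0.5)
  st <- init_beliefs(p0, ctl)
  st$a <- st$a + matrix(runif(6), 2, 3)
  a_before <- st$a
  expect_equal(observe_and_update(st, 1, "win", p0, ctl)$state$a, a_before)
  expect_equal(observe_and_update(st, 3, "loss", p0, ctl)$state$a, a_before)

  # full forgetting: history erased, only the prior plus this trial's
  # increment remains
  p1 <- agent_parameters(0.4, 0.7, 0.5, 1, 0.5)
  st <- init_beliefs(p1, ctl)
  st$a <- st$a + matrix(runif(6, 0.5, 2), 2, 3)
  res <- observe_and_update(st, 2, "win", p1, ctl)
  expected <- st$a0
  expected["win", 2] <- expected["win", 2] + 0.7
  expect_equal(res$state$a, expected)
})

test_that("decision noise rises after losses and falls after wins", {
  p <- mid_params()
  sim <- simulate_agent(p, make_schedule(15, 16, seed = 2), seed = 4)
  d <- sim$diagnostics
  n <- nrow(d)
  # within-block change of beta attributable to trial t's outcome
  same_block <- d$block[-n] == d$block[-1]
  dbeta <- d$beta[-1] - d$beta[-n]
  out_t <- sim$trials$outcome[-n]
  expect_gt(mean(dbeta[same_block & out_t == "loss"]), 0)
  expect_lt(mean(dbeta[same_block & out_t == "win"]), 0)
})

test_that("conservation holds along simulated trajectories", {
  p <- agent_parameters(0.5, 0.7, 0.4, 0.25, 0.6)
  ctl <- aif_control()
  st <- init_beliefs(p, ctl)
  set.seed(8)
  for (t in 1:60) {
    res <- observe_and_update(st, sample(3, 1),
                              sample(c("win", "loss"), 1), p, ctl)
    st <- res$state
    expect_lt(max(abs(colSums(st$A) - 1)), 1e-12)
    expect_equal(sum(st$pi), 1, tolerance = 1e-12)
    expect_gt(st$beta, 0)
  }
})

test_that("larger forgetting keeps beliefs closer to the prior", {
  tri <- sim_trials(n_blocks = 1, n_trials = 16, seed = 12)
  ctl <- aif_control()
  dist_to_prior <- function(om) {
    p <- agent_parameters(0.4, 0.6, 0.45, om, 0.57)
    st <- init_beliefs(p, ctl)
    for (t in seq_len(nrow(tri)))
      st <- observe_and_update(st, tri$choice[t], tri$outcome[t], p,
                               ctl)$state
    sum(abs(st$a - st$a0))
  }
  d <- vapply(c(0, 0.3, 0.6, 0.9), dist_to_prior, numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("forgetting produces recency bias in the next-choice preference", {
  # arm 1 wins early, arm 2 wins late; a forgetful agent should assign
  # more probability to repeating arm 2 afterwards
  hist <- make_trials(choice = c(1, 1, 1, 1, 2, 2),
                      outcome = c("win", "win", "win", "win", "win", "win"))
  probe <- rbind(hist, data.frame(block = 1, trial = 7, choice = 2,
                                  outcome = "win"))
  p_probe <- function(om) {
    par <- list(beta0 = 0.4, eta_win = 0.6, eta_loss = 0.45,
                omega = om, rho_p = 0.57)
    sequence_log_likelihood(par, probe)$action_prob[7]
  }
  expect_gt(p_probe(0.6), p_probe(0))
})

test_that("sequence likelihood matches symmetry and self-consistency", {
  # single trial from a fresh symmetric state
  one <- make_trials(2, "win")
  expect_equal(sequence_log_likelihood(mid_params(), one)$loglik,
               log(1 / 3), tolerance = 1e-12)

  # static agent: every trial contributes exactly log(1/3)
  p_static <- list(beta0 = 0.4, eta_win = 0, eta_loss = 0,
                   omega = 0, rho_p = 0.5)
  five <- make_trials(c(1, 3, 2, 2, 1),
                      c("win", "loss", "loss", "win", "win"))
  expect_equal(sequence_log_likelihood(p_static, five)$loglik,
               5 * log(1 / 3), tolerance = 1e-12)

  # exp(total) equals the product of per-trial action probabilities
  tri <- sim_trials(seed = 21)
  out <- sequence_log_likelihood(mid_params(), tri)
  expect_equal(out$loglik, sum(log(out$action_prob)), tolerance = 1e-10)
})

test_that("the R reference engine and the compiled filter agree", {
  set.seed(33)
  for (i in 1:8) {
    par <- random_aif_params()
    tri <- sim_trials(par, n_blocks = 3, n_trials = 10, seed = 100 + i)
    for (m in c("aif_full", "aif_no_forget", "aif_basic")) {
      pm <- par
      if (m != "aif_full") pm$omega <- NULL
      cpp <- sequence_log_likelihood(pm, tri, model = m)
      ref <- sequence_log_likelihood(pm, tri, model = m, engine = "r")
      expect_equal(cpp$loglik, ref$loglik, tolerance = 1e-10)
      expect_equal(cpp$action_prob, ref$action_prob, tolerance = 1e-10)
    }
  }
})

test_that("simulation has the right size, limits and determinism", {
  sch <- make_schedule(20, 16, seed = 7)
  sim <- simulate_agent(mid_params(), sch, seed = 3)
  expect_equal(nrow(sim$trials), 320L)
  expect_identical(simulate_agent(mid_params(), sch, seed = 3)$trials,
                   sim$trials)

  # noise-dominated limit: choice frequencies near uniform
  p_noisy <- list(beta0 = 1e4, eta_win = 0.5, eta_loss = 0.5,
                  omega = 0.1, rho_p = 0.5)
  big <- make_schedule(40, 250, seed = 1)
  simn <- simulate_agent(p_noisy, big, seed = 2)
  freq <- table(simn$trials$choice) / nrow(simn$trials)
  se3 <- 3 * sqrt((1 / 3) * (2 / 3) / nrow(simn$trials))
  expect_true(all(abs(freq - 1 / 3) < se3))

  # a deterministic fast learner exploits the best option late in blocks
  p_sharp <- list(beta0 = 0.15, eta_win = 0.9, eta_loss = 0.9,
                  omega = 0.05, rho_p = 0.5)
  sch2 <- make_schedule(50, 16, prob_menu = list(c(0.8, 0.5, 0.2)),
                        seed = 9)
  sims <- simulate_agent(p_sharp, sch2, seed = 10)
  best <- apply(sch2$probs, 1, which.max)
  late <- sims$trials$trial > 8
  hit <- mean(sims$trials$choice[late] == best[sims$trials$block[late]])
  expect_gt(hit, 0.55)
})

test_that("higher pessimism suppresses distinct-option visits", {
  sch <- make_schedule(500, 16, seed = 44)
  visits <- function(rho) {
    p <- list(beta0 = 0.3, eta_win = 0.6, eta_loss = 0.45,
              omega = 0.2, rho_p = rho)
    tri <- simulate_agent(p, sch, seed = 45)$trials
    mean(tapply(tri$choice, tri$block, function(x) length(unique(x))))
  }
  expect_lte(visits(0.8), visits(0.3))
})

test_that("the Rescorla-Wagner family honours its limits and nesting", {
  tri <- sim_trials(seed = 50)
  # eta = 0: static values, every choice at chance from neutral Q
  ll0 <- sequence_log_likelihood(list(beta0 = 0.5, eta = 0), tri,
                                 model = "rw_single")
  expect_equal(ll0$loglik, nrow(tri) * log(1 / 3), tolerance = 1e-10)

  # eta = 1: Q jumps to the reward; second trial of a repeated choice has
  # the hand-computed softmax probability
  two <- make_trials(c(2, 2), c("win", "win"))
  out <- sequence_log_likelihood(list(beta0 = 0.5, eta = 1), two,
                                 model = "rw_single")
  q <- c(0.5, 1, 0.5)  # after the first win, Q[2] jumped to r = 1
  expect_equal(out$action_prob[2],
               exp(q[2] / 0.5)[1] / sum(exp(q / 0.5)), tolerance = 1e-12)

  # dual-rate model with equal rates reproduces the single-rate model
  set.seed(60)
  for (i in 1:5) {
    eta <- runif(1, 0.1, 0.9); b <- exp(runif(1, log(0.2), log(2)))
    t2 <- sim_trials(model = "rw_dual",
                     params = list(beta0 = b, eta_win = 0.5,
                                   eta_loss = 0.3),
                     seed = 70 + i)
    l1 <- sequence_log_likelihood(list(beta0 = b, eta = eta), t2,
                                  model = "rw_single")$loglik
    l2 <- sequence_log_likelihood(list(beta0 = b, eta_win = eta,
                                       eta_loss = eta), t2,
                                  model = "rw_dual")$loglik
    expect_equal(l1, l2, tolerance = 1e-10)
  }
  expect_error(sequence_log_likelihood(mid_params(), tri, model = "nope"),
               "unknown model")
})
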