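# Model inversion: parameter transforms, MAP + Laplace behaviour against
# closed-form and grid-integration oracles, and the recovery harness.

test_that("parameter transforms are the documented bijections", {
  tf <- model_info("aif_full")$transform
  x <- c(beta0 = 1, eta_win = 0.5, eta_loss = 0.5, omega = 0.5,
         rho_p = 0.5)
  z <- transform_params(x, tf)
  expect_equal(unname(z[c("eta_win", "eta_loss", "omega", "beta0")]),
               c(0, 0, 0, 0))
  expect_equal(z[["rho_p"]], log(0.5))

  set.seed(2)
  worst <- 0
  for (i in 1:1000) {
    x <- c(beta0 = exp(runif(1, -3, 3)), eta_win = runif(1, 1e-4, 1 - 1e-4),
           eta_loss = runif(1, 1e-4, 1 - 1e-4),
           omega = runif(1, 1e-4, 1 - 1e-4), rho_p = runif(1, 1e-4, 0.999))
    back <- untransform_params(transform_params(x, tf), tf)
    worst <- max(worst, max(abs(back - x)))
  }
  expect_lt(worst, 1e-12)

  expect_error(transform_params(c(x, eta_win = 0)[-2], tf), "eta_win")
  expect_error(transform_params(replace(x, "beta0", -1), tf), "beta0")
})

test_that("a static noisy agent is fitted back to the chance floor", {
  p <- list(beta0 = 50, eta_win = 0.01, eta_loss = 0.01,
            omega = 0.01, rho_p = 0.5)
  tri <- simulate_agent(p, make_schedule(10, 16, seed = 31),
                        seed = 32)$trials
  fit <- fit_map(tri, n_starts = 2)
  expect_true(abs(fit$mean_action_prob - 1 / 3) < 0.04)
})

test_that("the optimum dominates the generating parameters", {
  set.seed(71)
  for (i in 1:4) {
    truth <- random_aif_params()
    tri <- simulate_agent(truth, make_schedule(8, 16, seed = 80 + i),
                          seed = 90 + i)$trials
    fit <- fit_map(tri, n_starts = 3, hessian = FALSE)
    pr <- default_priors("aif_full")
    tf <- model_info("aif_full")$transform
    th <- transform_params(truth, tf)
    lp_truth <- sequence_log_likelihood(truth, tri)$loglik +
      sum(dnorm(th, pr$mean, sqrt(pr$var), log = TRUE))
    expect_gte(fit$log_post, lp_truth - 1e-6)
  }
})

test_that("Laplace evidence matches grid integration on a 2-parameter slice", {
  truth <- list(beta0 = 0.4, eta_win = 0.6, eta_loss = 0.45, rho_p = 0.57)
  tri <- simulate_agent(truth, make_schedule(20, 16, seed = 55),
                        seed = 56, model = "aif_basic")$trials
  fixed <- list(eta_loss = 0.45, rho_p = 0.57)
  fit <- fit_map(tri, model = "aif_basic", fixed = fixed, n_starts = 3)
  expect_true(fit$converged)

  pr <- default_priors("aif_basic")
  rownames(pr) <- pr$param
  obj <- function(b, e) {
    ll <- sequence_log_likelihood(
      list(beta0 = exp(b), eta_win = plogis(e), eta_loss = 0.45,
           rho_p = 0.57), tri, model = "aif_basic")$loglik
    ll + dnorm(b, pr["beta0", "mean"], sqrt(pr["beta0", "var"]),
               log = TRUE) +
      dnorm(e, pr["eta_win", "mean"], sqrt(pr["eta_win", "var"]),
            log = TRUE)
  }
  ctr <- fit$estimate_t
  sdv <- sqrt(diag(fit$cov_t))
  bs <- seq(ctr["beta0"] - 6 * sdv["beta0"], ctr["beta0"] + 6 * sdv["beta0"],
            length.out = 81)
  es <- seq(ctr["eta_win"] - 6 * sdv["eta_win"],
            ctr["eta_win"] + 6 * sdv["eta_win"], length.out = 81)
  lp <- outer(bs, es, Vectorize(obj))
  cell <- diff(bs)[1] * diff(es)[1]
  grid_log_ev <- log(sum(exp(lp - max(lp)))) + max(lp) + log(cell)
  expect_lt(abs(fit$log_evidence - grid_log_ev), 1)
})

test_that("the recovery harness reports degenerate samplers as missing", {
  sampler <- function(n) {
    out <- broad_parameter_sampler(n)
    out$omega <- 0.3  # zero-variance dimension
    out
  }
  rs <- recovery_study(n_agents = 10, n_blocks = 3, n_trials = 8,
                       sampler = sampler, seed = 3,
                       fit_args = list(n_starts = 2,
                                       optim_control = list(maxit = 300)))
  expect_true(is.na(rs$correlations[["omega"]]))
  expect_true(all(is.finite(rs$correlations[c("beta0", "eta_win")])))
})

test_that("identical estimates give unit recovery correlations", {
  # harness identity check: feed the correlation step a table in which
  # estimates equal the generative values
  rs <- recovery_study(n_agents = 10, n_blocks = 2, n_trials = 6, seed = 4,
                       fit_args = list(n_starts = 1,
                                       optim_control = list(maxit = 50)))
  tab <- rs$table
  tab$est_t <- tab$true_t
  r <- sapply(split(tab, tab$param),
              function(d) cor(d$true_t, d$est_t))
  expect_true(all(abs(r - 1) < 1e-12))
})

test_that("model evidence penalises unneeded complexity", {
  # data from the single-rate model: the nested simpler model should win
  # the evidence comparison against the dual-rate model most of the time
  set.seed(12)
  wins <- 0L
  n_rep <- 50L
  for (i in 1:n_rep) {
    truth <- list(beta0 = exp(runif(1, log(0.25), log(1))),
                  eta = runif(1, 0.2, 0.8))
    tri <- simulate_agent(truth, make_schedule(8, 16, seed = 300 + i),
                          seed = 400 + i, model = "rw_single")$trials
    f1 <- fit_map(tri, model = "rw_single", n_starts = 2, seed = i)
    f2 <- fit_map(tri, model = "rw_dual", n_starts = 2, seed = i)
    if (f1$log_evidence >= f2$log_evidence) wins <- wins + 1L
  }
  expect_gt(wins, n_rep / 2)
})

test_that("low-noise agents are predicted well above chance", {
  set.seed(91)
  probs <- replicate(5, {
    p <- list(beta0 = exp(runif(1, log(0.15), log(0.5))),
              eta_win = runif(1, 0.4, 0.9), eta_loss = runif(1, 0.4, 0.9),
              omega = runif(1, 0.05, 0.4), rho_p = runif(1, 0.4, 0.7))
    tri <- simulate_agent(p, make_schedule(10, 16,
                                           seed = sample.int(1e6, 1)),
                          seed = sample.int(1e6, 1))$trials
    fit_map(tri, n_starts = 2, hessian = FALSE)$mean_action_prob
  })
  expect_gt(mean(probs), 0.5)
})
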