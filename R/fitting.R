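# Model inversion: MAP estimation in transformed parameter space with a
# Laplace approximation to the log model evidence, plus the
# simulate-then-refit parameter recovery study.

#' Transform parameters between native and fitting space
#'
#' Learning and forgetting rates are fitted in logit space; decision noise,
#' pessimism and reward sensitivity in log space.
#'
#' @param params Named numeric vector of native-space values.
#' @param transforms Named character vector (`"log"` or `"logit"`) per
#'   parameter, e.g. `model_info(model)$transform`.
#' @return Named numeric vector in the other space.
#' @export
transform_params <- function(params, transforms) {
  params <- unlist(params)[names(transforms)]
  out <- numeric(length(transforms))
  names(out) <- names(transforms)
  for (nm in names(transforms)) {
    x <- params[[nm]]
    if (transforms[[nm]] == "logit") {
      if (x <= 0 || x >= 1)
        stop(sprintf("`%s` must lie strictly inside (0, 1)", nm))
      out[nm] <- qlogis(x)
    } else {
      if (x <= 0) stop(sprintf("`%s` must be strictly positive", nm))
      out[nm] <- log(x)
    }
  }
  out
}

#' @rdname transform_params
#' @export
untransform_params <- function(params, transforms) {
  params <- unlist(params)[names(transforms)]
  out <- numeric(length(transforms))
  names(out) <- names(transforms)
  for (nm in names(transforms)) {
    out[nm] <- if (transforms[[nm]] == "logit") plogis(params[[nm]])
               else exp(params[[nm]])
  }
  out
}

#' Default priors in transformed space
#'
#' Weakly informative Gaussians: mean 0, variance 1/2 for every parameter,
#' except pessimism whose log-space prior is centred on `log(0.5)` (a mean
#' of 0 would place the prior loss probability at 1, outside its domain).
#'
#' @param model Model id.
#' @return Data frame with columns `param`, `transform`, `mean`, `var`.
#' @export
default_priors <- function(model = "aif_full") {
  info <- model_info(model)
  mu <- setNames(rep(0, length(info$params)), info$params)
  if ("rho_p" %in% info$params) mu["rho_p"] <- log(0.5)
  data.frame(param = info$params,
             transform = unname(info$transform[info$params]),
             mean = unname(mu),
             var = 0.5,
             stringsAsFactors = FALSE)
}

#' Fit a registered model to one participant by MAP + Laplace
#'
#' Maximises log-likelihood plus log-prior in transformed space with
#' multi-start Nelder-Mead, takes the covariance from the regularised
#' negative inverse Hessian (central finite differences) at the optimum,
#' and approximates the log evidence by the Laplace formula
#' `log p(y) ~ log p(y, theta*) + d/2 log(2 pi) + 1/2 log |Sigma|`.
#'
#' @param trials Trial data frame for one participant.
#' @param model Model id.
#' @param priors Prior specification as from [default_priors()].
#' @param fixed Optional named list of native-space values to hold fixed
#'   (removed from the free parameter set).
#' @param n_starts Number of optimisation starts (prior mean plus seeded
#'   Gaussian perturbations).
#' @param seed Integer seed controlling the starts.
#' @param hessian Compute the Hessian/covariance/evidence? Skipping it
#'   speeds up large cohort fits that only need point estimates.
#' @param control Agent constants, see [aif_control()].
#' @param optim_control Passed to [stats::optim()] (Nelder-Mead);
#'   defaults allow up to 2000 function evaluations per start.
#' @return An `aif_fit` object: posterior mode in transformed
#'   (`estimate_t`) and native (`estimate`) space, covariance `cov_t`,
#'   `log_evidence`, `loglik`, per-trial `action_prob`, `accuracy`
#'   (modal-action agreement), `mean_action_prob`, convergence flags.
#' @export
fit_map <- function(trials, model = "aif_full", priors = NULL,
                    fixed = NULL, n_starts = 4, seed = 1L,
                    hessian = TRUE, control = aif_control(),
                    optim_control = list(maxit = 2000, reltol = 1e-8)) {
  info <- model_info(model)
  if (is.null(priors)) priors <- default_priors(model)
  stopifnot(all(info$params %in% priors$param), all(priors$var > 0))
  enc <- encode_trials(trials)
  if (length(unique(enc$block)) < 1L) stop("need at least one block")

  free <- setdiff(info$params, names(fixed))
  if (!length(free)) stop("no free parameters left to fit")
  pr <- priors[match(free, priors$param), ]
  pmu <- pr$mean
  psd <- sqrt(pr$var)
  tf <- info$transform[free]

  nat_fixed <- as.list(fixed)
  objective <- function(theta) {
    nat <- untransform_params(setNames(theta, free), tf)
    out <- model_filter(model, c(as.list(nat), nat_fixed), enc, control)
    ll <- out$loglik
    if (!is.finite(ll)) return(1e10)
    lp <- sum(dnorm(theta, pmu, psd, log = TRUE))
    -(ll + lp)
  }

  # Candidate pool: prior mean plus seeded over-dispersed draws, screened
  # by the objective; Nelder-Mead runs from the best `n_starts` of them,
  # with a final restart from the incumbent to escape collapsed simplexes.
  n_pool <- max(8 * n_starts, 24)
  pool <- with_seed(seed, {
    s <- matrix(rep(pmu, n_pool), nrow = n_pool, byrow = TRUE)
    for (i in 2:n_pool)
      s[i, ] <- pmu + rnorm(length(free), 0, 2 * psd)
    s
  })
  pool_val <- apply(pool, 1, objective)
  starts <- pool[order(pool_val)[seq_len(n_starts)], , drop = FALSE]

  best <- NULL
  for (i in seq_len(n_starts)) {
    res <- tryCatch(
      optim(starts[i, ], objective, method = "Nelder-Mead",
            control = optim_control),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("all optimisation starts failed for model ", model)
  res <- tryCatch(
    optim(best$par, objective, method = "Nelder-Mead",
          control = optim_control),
    error = function(e) NULL)
  if (!is.null(res) && res$value < best$value) best <- res

  theta <- setNames(best$par, free)
  converged <- best$convergence == 0
  log_post <- -best$value
  nat <- untransform_params(theta, tf)

  cov_t <- NULL
  log_evidence <- NA_real_
  regularized <- FALSE
  if (hessian) {
    H <- fd_hessian(function(th) -objective(th), theta, h = 1e-4)
    P <- -H  # precision of the Laplace posterior
    eg <- eigen((P + t(P)) / 2, symmetric = TRUE)
    if (any(eg$values < 1e-8)) regularized <- TRUE
    ev <- pmax(eg$values, 1e-8)
    cov_t <- eg$vectors %*% diag(1 / ev, length(ev)) %*% t(eg$vectors)
    dimnames(cov_t) <- list(free, free)
    log_evidence <- log_post + 0.5 * length(free) * log(2 * pi) -
      0.5 * sum(log(ev))
  }

  fit_out <- model_filter(model, c(as.list(nat), nat_fixed), enc, control)
  modal <- max.col(fit_out$pi, ties.method = "first")
  structure(list(
    model = model,
    estimate_t = theta,
    estimate = nat,
    fixed = nat_fixed,
    cov_t = cov_t,
    loglik = fit_out$loglik,
    log_post = log_post,
    log_evidence = log_evidence,
    action_prob = fit_out$action_prob,
    accuracy = mean(modal == enc$choice + 1L),
    mean_action_prob = mean(fit_out$action_prob),
    converged = converged,
    regularized = regularized,
    n_trials = length(enc$block),
    n_starts = n_starts, seed = seed,
    priors = priors), class = "aif_fit")
}

#' @export
print.aif_fit <- function(x, ...) {
  cat(sprintf("MAP fit of '%s' on %d trials\n", x$model, x$n_trials))
  est <- rbind(native = x$estimate, transformed = x$estimate_t)
  print(round(est, 4))
  cat(sprintf(
    "log evidence %.2f | loglik %.2f | accuracy %.3f | mean P(choice) %.3f\n",
    x$log_evidence, x$loglik, x$accuracy, x$mean_action_prob))
  if (!x$converged) cat("WARNING: optimiser did not report convergence\n")
  if (x$regularized) cat("note: Hessian regularised to positive definite\n")
  invisible(x)
}

# Central finite-difference Hessian of f at x (step h per coordinate).
fd_hessian <- function(f, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(NA_real_, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < d) {
      for (j in (i + 1):d) {
        ej <- replace(numeric(d), j, h)
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) -
             f(x - ei + ej) + f(x - ei - ej)) / (4 * h^2)
      }
    }
  }
  H
}

#' Broad parameter sampler for recovery studies
#'
#' Rates and probabilities uniform over the central 90% of (0, 1);
#' initial decision noise log-uniform on `[0.1, 3]`; reward sensitivity
#' log-uniform on `[0.5, 2]`. Draws from the current RNG stream.
#'
#' @param n Number of agents.
#' @param model Model id.
#' @return Data frame of native-space parameters, one row per agent.
#' @export
broad_parameter_sampler <- function(n, model = "aif_full") {
  info <- model_info(model)
  draw1 <- function(nm) {
    switch(info$transform[[nm]],
           logit = runif(n, 0.05, 0.95),
           log = if (nm == "beta0") exp(runif(n, log(0.1), log(3)))
                 else if (nm == "rs") exp(runif(n, log(0.5), log(2)))
                 else runif(n, 0.05, 0.95))
  }
  out <- as.data.frame(lapply(setNames(info$params, info$params), draw1))
  out
}

#' Simulate-then-refit parameter recovery study
#'
#' Draws generative parameters from `sampler`, simulates each agent on its
#' own randomised schedule, refits by [fit_map()], and correlates
#' generative with estimated values per parameter in transformed space.
#'
#' @param n_agents Number of simulated agents (>= 10).
#' @param model Model id.
#' @param n_blocks,n_trials,prob_menu Schedule settings, see
#'   [make_schedule()].
#' @param sampler Function `n -> data.frame` of native parameters;
#'   defaults to [broad_parameter_sampler()].
#' @param seed Integer seed governing sampling, schedules, simulation and
#'   fit starts.
#' @param fit_args List of extra arguments to [fit_map()].
#' @param control Agent constants used for both simulation and fitting.
#' @param progress Print a progress line every 25 agents?
#' @return A `recovery_study`: named `correlations` (transformed space),
#'   long `table` of generative/estimated values, `n_failed` fit count.
#' @export
recovery_study <- function(n_agents = 200, model = "aif_full",
                           n_blocks = 20, n_trials = 16,
                           prob_menu = default_prob_menu(),
                           sampler = NULL, seed = 1L, fit_args = list(),
                           control = aif_control(), progress = FALSE) {
  if (n_agents < 10) stop("`n_agents` must be at least 10")
  info <- model_info(model)
  if (is.null(sampler))
    sampler <- function(n) broad_parameter_sampler(n, model)

  res <- with_seed(seed, {
    truth <- sampler(n_agents)
    stopifnot(all(info$params %in% names(truth)))
    sched_seeds <- draw_seeds(n_agents)
    sim_seeds <- draw_seeds(n_agents)
    list(truth = truth, sched_seeds = sched_seeds, sim_seeds = sim_seeds)
  })
  truth <- res$truth

  rows <- vector("list", n_agents)
  n_failed <- 0L
  for (i in seq_len(n_agents)) {
    sched <- make_schedule(n_blocks, n_trials, prob_menu,
                           seed = res$sched_seeds[i])
    sim <- simulate_agent(as.list(truth[i, ]), sched,
                          seed = res$sim_seeds[i], model = model,
                          control = control)
    fit <- tryCatch(
      do.call(fit_map, c(list(trials = sim$trials, model = model,
                              seed = res$sim_seeds[i], hessian = FALSE,
                              control = control),
                         fit_args)),
      error = function(e) NULL)
    ok <- !is.null(fit) && fit$converged
    if (!ok) n_failed <- n_failed + 1L
    est <- if (is.null(fit)) setNames(rep(NA_real_, length(info$params)),
                                      info$params) else fit$estimate
    est_t <- if (is.null(fit)) est else fit$estimate_t
    true_t <- transform_params(truth[i, info$params], info$transform)
    rows[[i]] <- data.frame(
      agent = i, param = info$params,
      true_native = as.numeric(truth[i, info$params]),
      est_native = as.numeric(est[info$params]),
      true_t = as.numeric(true_t),
      est_t = as.numeric(est_t[info$params]),
      converged = ok)
    if (progress && i %% 25 == 0)
      message(sprintf("recovery: %d / %d agents fitted", i, n_agents))
  }
  table <- do.call(rbind, rows)
  ok <- table$converged & is.finite(table$est_t)
  correlations <- sapply(info$params, function(pm) {
    sub <- table[table$param == pm & ok, ]
    if (nrow(sub) < 3 || sd(sub$true_t) == 0 || sd(sub$est_t) == 0)
      return(NA_real_)
    cor(sub$true_t, sub$est_t)
  })
  structure(list(correlations = correlations, table = table,
                 n_agents = n_agents, n_failed = n_failed,
                 model = model, seed = seed),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf(
    "Parameter recovery for '%s': %d agents (%d failed fits)\n",
    x$model, x$n_agents, x$n_failed))
  cat("Generative vs estimated Pearson r (transformed space):\n")
  print(round(x$correlations, 3))
  invisible(x)
}

#' Scatter plot of a recovery study
#'
#' @param x A `recovery_study`.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_recovery <- function(x) {
  stopifnot(inherits(x, "recovery_study"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_recovery requires ggplot2")
  true_t <- est_t <- NULL  # NSE bindings for ggplot2
  tab <- x$table[x$table$converged, ]
  ggplot2::ggplot(tab, ggplot2::aes(x = true_t, y = est_t)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::facet_wrap(~param, scales = "free") +
    ggplot2::labs(x = "generative (transformed)",
                  y = "estimated (transformed)")
}
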