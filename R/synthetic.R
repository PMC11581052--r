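# Synthetic cohorts: the generative population lives in transformed
# parameter space; native-space summary targets (group means/SDs) are
# mapped to transformed-space Gaussians by quadrature-based moment
# matching. Reaction times are coupled to model-derived confidence.

# Native-space parameter summaries (mean, SD) per emulated group for the
# winning model, and cohort demographics used by the paper-like preset.
cohort_reference <- function() {
  param_order <- c("beta0", "eta_win", "eta_loss", "omega", "rho_p")
  means <- rbind(
    HC   = c(beta0 = 0.40, eta_win = 0.57, eta_loss = 0.42,
             omega = 0.28, rho_p = 0.57),
    iAD  = c(beta0 = 0.38, eta_win = 0.59, eta_loss = 0.45,
             omega = 0.38, rho_p = 0.59),
    iSUD = c(beta0 = 0.45, eta_win = 0.60, eta_loss = 0.36,
             omega = 0.35, rho_p = 0.57))
  sds <- rbind(
    HC   = c(beta0 = 0.18, eta_win = 0.25, eta_loss = 0.34,
             omega = 0.17, rho_p = 0.12),
    iAD  = c(beta0 = 0.18, eta_win = 0.28, eta_loss = 0.34,
             omega = 0.17, rho_p = 0.15),
    iSUD = c(beta0 = 0.27, eta_win = 0.26, eta_loss = 0.24,
             omega = 0.14, rho_p = 0.14))
  demo <- data.frame(
    label = c("HC", "iAD", "iSUD"),
    n = c(54L, 242L, 147L),
    male_rate = c(0.4444, 0.2769, 0.4898),
    age_mean = c(32.27, 35.72, 34.05),
    age_sd = c(11.35, 11.36, 9.17),
    stringsAsFactors = FALSE)
  list(param_order = param_order, means = means[, param_order],
       sds = sds[, param_order], demo = demo)
}

#' Match native-space moments with a transformed-space Gaussian
#'
#' Finds the Gaussian N(mu, sigma^2) in transformed space whose induced
#' native-space mean and SD (through the inverse transform, truncated to
#' the parameter's legal domain) match the targets. Uses a fixed
#' standard-normal quadrature grid, so the result is deterministic.
#'
#' @param native_mean,native_sd Target native-space moments.
#' @param transform `"logit"` or `"log"`.
#' @param upper Upper domain bound for log-space parameters that live in
#'   (0, 1) (e.g. pessimism); `Inf` otherwise.
#' @return List with `mu`, `sigma`, the achieved moments, and the maximum
#'   relative error.
#' @export
match_transformed_moments <- function(native_mean, native_sd, transform,
                                      upper = Inf) {
  stopifnot(native_mean > 0, native_sd > 0,
            transform %in% c("logit", "log"))
  u <- seq(-8, 8, length.out = 3201)
  w <- dnorm(u)
  w <- w / sum(w)
  finv <- if (transform == "logit") plogis else exp
  moments <- function(mu, sigma) {
    x <- finv(mu + sigma * u)
    keep <- x < upper
    wk <- w[keep] / sum(w[keep])
    xk <- x[keep]
    m <- sum(wk * xk)
    list(mean = m, sd = sqrt(max(sum(wk * (xk - m)^2), 1e-300)))
  }
  obj <- function(p) {
    mm <- moments(p[1], exp(p[2]))
    (mm$mean / native_mean - 1)^2 + (mm$sd / native_sd - 1)^2
  }
  start <- c(if (transform == "logit") qlogis(min(max(native_mean, 1e-3),
                                                  1 - 1e-3))
             else log(native_mean),
             log(0.5))
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  mm <- moments(fit$par[1], exp(fit$par[2]))
  list(mu = fit$par[1], sigma = exp(fit$par[2]),
       achieved_mean = mm$mean, achieved_sd = mm$sd,
       rel_error = max(abs(mm$mean / native_mean - 1),
                       abs(mm$sd / native_sd - 1)))
}

#' Construct a cohort design
#'
#' @param groups Data frame with columns `label`, `n`, `male_rate`,
#'   `age_mean`, `age_sd`.
#' @param param_means,param_sds Matrices (groups x parameters) of
#'   transformed-space population means and SDs for the winning model's
#'   parameters, rows matching `groups$label`.
#' @param rt RT model coefficients: list with `intercept` (ms),
#'   `entropy_slope` (ms per nat of choice uncertainty), `update_slope`
#'   (ms per unit of negated belief update), `noise_sd` (ms), `floor` (ms).
#' @param n_blocks,n_trials,prob_menu Task schedule settings.
#' @param sampler `"gaussian"` (transformed-space Gaussians per group) or
#'   `"broad"` (the recovery sampler, ignoring group moments).
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(groups, param_means, param_sds,
                          rt = list(intercept = 500, entropy_slope = 250,
                                    update_slope = 100, noise_sd = 150,
                                    floor = 150),
                          n_blocks = 20, n_trials = 16,
                          prob_menu = default_prob_menu(),
                          sampler = "gaussian") {
  stopifnot(all(c("label", "n", "male_rate", "age_mean", "age_sd") %in%
                  names(groups)),
            all(groups$n >= 1), rt$noise_sd > 0)
  if (sampler == "gaussian") {
    stopifnot(is.matrix(param_means), is.matrix(param_sds),
              nrow(param_means) == nrow(groups),
              all(param_sds >= 0))
  }
  structure(list(groups = groups, param_means = param_means,
                 param_sds = param_sds, rt = rt, n_blocks = n_blocks,
                 n_trials = n_trials, prob_menu = prob_menu,
                 sampler = sampler),
            class = "cohort_design")
}

#' Preset cohort designs
#'
#' \describe{
#'   \item{paper_like}{Three groups (HC-like n = 54, iAD-like n = 242,
#'     iSUD-like n = 147) with native-space parameter means/SDs matching
#'     the reference group summaries by quadrature moment matching, and
#'     matching demographics.}
#'   \item{null_groups}{Same sizes, all groups share the pooled
#'     parameter distribution.}
#'   \item{strong_effects}{Group separations in transformed space doubled
#'     around the (unweighted) grand mean.}
#'   \item{recovery_broad}{One group of 200 agents drawn from the broad
#'     recovery sampler.}
#' }
#'
#' @param name Preset name.
#' @return A `cohort_design`.
#' @export
preset_designs <- function(name = c("paper_like", "null_groups",
                                    "strong_effects", "recovery_broad")) {
  name <- match.arg(name)
  ref <- cohort_reference()
  tf <- model_info("aif_full")$transform

  if (name == "recovery_broad") {
    groups <- data.frame(label = "sim", n = 200L, male_rate = 0.5,
                         age_mean = 34, age_sd = 10,
                         stringsAsFactors = FALSE)
    return(cohort_design(groups, param_means = NULL, param_sds = NULL,
                         sampler = "broad"))
  }

  mus <- sds <- matrix(NA_real_, 3, length(ref$param_order),
                       dimnames = list(rownames(ref$means),
                                       ref$param_order))
  for (g in rownames(ref$means)) {
    for (pm in ref$param_order) {
      upper <- if (pm == "rho_p") 1 else Inf
      mm <- match_transformed_moments(ref$means[g, pm], ref$sds[g, pm],
                                      tf[[pm]], upper = upper)
      mus[g, pm] <- mm$mu
      sds[g, pm] <- mm$sigma
    }
  }
  if (name == "null_groups") {
    grand_mu <- colMeans(mus)
    grand_sd <- colMeans(sds)
    for (g in rownames(mus)) {
      mus[g, ] <- grand_mu
      sds[g, ] <- grand_sd
    }
  } else if (name == "strong_effects") {
    grand_mu <- colMeans(mus)
    mus <- sweep(sweep(mus, 2, grand_mu, "-") * 2, 2, grand_mu, "+")
  }
  cohort_design(ref$demo, mus, sds)
}

#' Sample a full synthetic cohort
#'
#' Per participant: draw transformed-space parameters from the group's
#' Gaussian (redrawing the rare draws that land outside a parameter's
#' native domain), simulate the task with the active inference agent on a
#' fresh randomised schedule, and generate reaction times as
#' `intercept + entropy_slope * entropy(t) +
#'  update_slope * (-belief_update(t - 1)) + noise`, floored at
#' `rt$floor` ms (the update term is 0 on first trials of blocks).
#' Fully deterministic given `seed`.
#'
#' @param design A [cohort_design()] (e.g. from [preset_designs()]).
#' @param seed Integer seed.
#' @param keep_diagnostics Keep the generative per-trial diagnostics
#'   (entropy, belief update, ...) in the result?
#' @return A `synthetic_cohort`: list with `trials` (observable data),
#'   `truth` (per-participant generative parameters, native and
#'   transformed, plus demographics) and optionally `diagnostics`.
#' @export
sample_cohort <- function(design, seed = 1L, keep_diagnostics = TRUE) {
  stopifnot(inherits(design, "cohort_design"))
  params <- c("beta0", "eta_win", "eta_loss", "omega", "rho_p")
  tf <- model_info("aif_full")$transform

  with_seed(seed, {
    trial_rows <- list()
    diag_rows <- list()
    truth_rows <- list()
    pid <- 0L
    for (g in seq_len(nrow(design$groups))) {
      grp <- design$groups[g, ]
      for (i in seq_len(grp$n)) {
        pid <- pid + 1L
        id <- sprintf("S%04d", pid)

        if (design$sampler == "broad") {
          nat <- unlist(broad_parameter_sampler(1)[1, params])
          theta <- transform_params(nat, tf)
        } else {
          for (try in 1:100) {
            theta <- setNames(rnorm(length(params),
                                    design$param_means[g, params],
                                    design$param_sds[g, params]), params)
            nat <- untransform_params(theta, tf)
            if (nat[["rho_p"]] < 1) break
            if (try == 100) stop("could not draw valid parameters")
          }
        }

        age <- min(55, max(18, rnorm(1, grp$age_mean, grp$age_sd)))
        sex <- if (runif(1) < grp$male_rate) "male" else "female"
        seeds <- draw_seeds(2)
        sched <- make_schedule(design$n_blocks, design$n_trials,
                               design$prob_menu, seed = seeds[1])
        sim <- simulate_agent(as.list(nat), sched, seed = seeds[2])

        d <- sim$diagnostics
        n <- nrow(d)
        prev_upd <- c(0, -d$belief_update[-n])
        prev_upd[d$trial == 1] <- 0
        rt <- design$rt$intercept +
          design$rt$entropy_slope * d$entropy +
          design$rt$update_slope * prev_upd +
          rnorm(n, 0, design$rt$noise_sd)
        rt <- pmax(design$rt$floor, rt)

        tri <- sim$trials
        tri$rt_ms <- rt
        tri <- cbind(participant_id = id, group = grp$label, tri,
                     stringsAsFactors = FALSE)
        trial_rows[[pid]] <- tri
        if (keep_diagnostics)
          diag_rows[[pid]] <- cbind(participant_id = id, d,
                                    stringsAsFactors = FALSE)
        tr <- data.frame(participant_id = id, group = grp$label,
                         age = age, sex = sex, stringsAsFactors = FALSE)
        for (pm in params) tr[[pm]] <- nat[[pm]]
        for (pm in params) tr[[paste0(pm, "_t")]] <- theta[[pm]]
        truth_rows[[pid]] <- tr
      }
    }
    structure(list(trials = do.call(rbind, trial_rows),
                   truth = do.call(rbind, truth_rows),
                   diagnostics = if (keep_diagnostics)
                     do.call(rbind, diag_rows) else NULL,
                   design = design, seed = seed),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d participants, %d trials each (seed %d)\n",
    nrow(x$truth), x$design$n_blocks * x$design$n_trials, x$seed))
  print(table(x$truth$group))
  invisible(x)
}

#' Fit every participant of a cohort and tabulate estimates
#'
#' @param trials Cohort trial data frame with `participant_id` (and
#'   optionally `group`).
#' @param model Model id.
#' @param fit_args Extra arguments for [fit_map()].
#' @param progress Print a line every 50 participants?
#' @return Data frame with one row per participant: native estimates,
#'   transformed estimates (`*_t`), first-level posterior variances
#'   (`*_var`, when the Hessian is computed), accuracy, mean action
#'   probability, log evidence and convergence flag.
#' @export
fit_cohort <- function(trials, model = "aif_full", fit_args = list(),
                       progress = FALSE) {
  stopifnot("participant_id" %in% names(trials))
  info <- model_info(model)
  ids <- unique(trials$participant_id)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    tri <- trials[trials$participant_id == ids[i], ]
    fit <- do.call(fit_map, c(list(trials = tri, model = model), fit_args))
    row <- data.frame(participant_id = ids[i], stringsAsFactors = FALSE)
    if ("group" %in% names(tri)) row$group <- tri$group[1]
    for (pm in info$params) row[[pm]] <- fit$estimate[[pm]]
    for (pm in info$params) row[[paste0(pm, "_t")]] <- fit$estimate_t[[pm]]
    if (!is.null(fit$cov_t))
      for (pm in info$params)
        row[[paste0(pm, "_var")]] <- fit$cov_t[pm, pm]
    row$accuracy <- fit$accuracy
    row$mean_action_prob <- fit$mean_action_prob
    row$log_evidence <- fit$log_evidence
    row$converged <- fit$converged
    rows[[i]] <- row
    if (progress && i %% 50 == 0)
      message(sprintf("fit_cohort: %d / %d participants", i, length(ids)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
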