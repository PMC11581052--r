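# Random-effects Bayesian model selection over per-participant log
# evidences: variational Dirichlet updates, Monte-Carlo exceedance
# probabilities, and a free-energy Bayes omnibus risk protecting against
# the equal-frequency null.

#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across participants.
#' Dirichlet weights over model frequencies are obtained by the standard
#' variational scheme; exceedance probabilities by Monte-Carlo sampling
#' from the Dirichlet posterior; the Bayes omnibus risk (BOR) compares the
#' free energy of the random-effects model against the null hypothesis of
#' equal model frequencies; and the protected exceedance probability is
#' `pxp = xp * (1 - BOR) + BOR / K`.
#'
#' @param lme Numeric matrix of approximate log model evidences,
#'   participants in rows, models in columns (>= 2 of each). Column names
#'   are used as model ids.
#' @param alpha0 Dirichlet prior weight per model (default 1: uniform over
#'   frequencies).
#' @param n_samples Monte-Carlo draws for the exceedance probabilities.
#' @param seed Integer seed for the Monte-Carlo step.
#' @param tol,max_iter Convergence control of the variational updates.
#' @return A `bms_result`: `alpha`, expected frequencies `exp_freq`,
#'   `xp`, `bor`, `pxp`, and per-participant model attributions `g`.
#' @export
rfx_bms <- function(lme, alpha0 = 1, n_samples = 1e6, seed = 1L,
                    tol = 1e-8, max_iter = 1000) {
  lme <- as.matrix(lme)
  if (any(!is.finite(lme))) stop("log evidences must all be finite")
  n <- nrow(lme)
  K <- ncol(lme)
  if (K < 2) stop("need at least 2 models")
  if (n < 2) stop("need at least 2 participants")
  models <- colnames(lme) %||% paste0("model", seq_len(K))

  a0 <- rep(alpha0, K)
  alpha <- a0 + n / K
  g <- matrix(1 / K, n, K)
  for (it in seq_len(max_iter)) {
    Elnr <- digamma(alpha) - digamma(sum(alpha))
    u <- sweep(lme, 2, Elnr, "+")
    u <- exp(u - apply(u, 1, max))
    g <- u / rowSums(u)
    alpha_new <- a0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }

  # Exceedance probabilities by sampling from Dirichlet(alpha).
  xp <- with_seed(seed, {
    counts <- numeric(K)
    left <- n_samples
    while (left > 0) {
      m <- min(left, 100000L)
      draws <- matrix(rgamma(m * K, shape = rep(alpha, each = m)), m, K)
      top <- max.col(draws, ties.method = "random")
      counts <- counts + tabulate(top, K)
      left <- left - m
    }
    counts / n_samples
  })

  # Free energy of the random-effects model...
  Elnr <- digamma(alpha) - digamma(sum(alpha))
  kl_dir <- lgamma(sum(alpha)) - sum(lgamma(alpha)) -
    lgamma(sum(a0)) + sum(lgamma(a0)) +
    sum((alpha - a0) * (digamma(alpha) - digamma(sum(alpha))))
  gl <- g * log(pmax(g, 1e-300))
  F1 <- sum(g * sweep(lme, 2, Elnr, "+")) - sum(gl) - kl_dir
  # ... against the equal-frequency null.
  F0 <- sum(apply(lme, 1, logsumexp) - log(K))
  bor <- 1 / (1 + exp(F1 - F0))

  pxp <- xp * (1 - bor) + bor / K
  structure(list(models = models,
                 alpha = setNames(alpha, models),
                 exp_freq = setNames(alpha / sum(alpha), models),
                 xp = setNames(xp, models),
                 bor = bor,
                 pxp = setNames(pxp, models),
                 g = g, F1 = F1, F0 = F0,
                 n_participants = n),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat(sprintf(
    "Random-effects BMS over %d participants, %d models (BOR = %.3f)\n",
    x$n_participants, length(x$models), x$bor))
  print(round(rbind(`expected freq` = x$exp_freq, xp = x$xp,
                    pxp = x$pxp), 4))
  invisible(x)
}

#' Fit several models to a cohort and collect log evidences
#'
#' Convenience wrapper: fits each registered model id to every participant
#' in a cohort trial table and returns the participants x models matrix of
#' Laplace log evidences, ready for [rfx_bms()].
#'
#' @param trials Cohort trial data frame with a `participant_id` column.
#' @param models Character vector of model ids.
#' @param fit_args Extra arguments for [fit_map()].
#' @param progress Print one line per participant?
#' @return Matrix of log evidences with participant ids as row names.
#' @export
evidence_matrix <- function(trials, models, fit_args = list(),
                            progress = FALSE) {
  stopifnot("participant_id" %in% names(trials), length(models) >= 2)
  ids <- unique(trials$participant_id)
  out <- matrix(NA_real_, length(ids), length(models),
                dimnames = list(ids, models))
  for (i in seq_along(ids)) {
    tri <- trials[trials$participant_id == ids[i], ]
    for (m in models) {
      fit <- do.call(fit_map, c(list(trials = tri, model = m), fit_args))
      out[i, m] <- fit$log_evidence
    }
    if (progress)
      message(sprintf("evidence: participant %d / %d", i, length(ids)))
  }
  out
}
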