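# Group-level inference on fitted parameters: frequentist GLMs with
# sum-coded group and EMM contrasts, and a precision-weighted Bayesian
# GLM with reduced-model search (parametric-empirical-Bayes style).

# Internal: centred/coded covariate columns. Sex is coded +1/2 (male),
# -1/2 (female); age is mean-centred, keeping the intercept at the
# sample-typical participant.
code_covariates <- function(data, covariates) {
  out <- data
  used <- character(0)
  if ("age" %in% covariates && "age" %in% names(data)) {
    out$age_c <- data$age - mean(data$age)
    used <- c(used, "age_c")
  }
  if ("sex" %in% covariates && "sex" %in% names(data)) {
    s <- data$sex
    if (is.character(s) || is.factor(s))
      s <- as.numeric(as.character(s) == "male")
    out$sex_c <- s - 0.5
    used <- c(used, "sex_c")
  }
  list(data = out, terms = used)
}

#' Group GLM with sum coding and EMM contrasts
#'
#' Ordinary least squares of one outcome on a sum-coded group factor plus
#' centred age and sex, the omnibus group F from comparing the full model
#' against the group-dropped model, partial eta-squared from the sums of
#' squares, estimated marginal means at the covariate means, and all
#' pairwise EMM contrasts (unadjusted t tests).
#'
#' @param data Data frame containing `outcome`, `group` and the covariate
#'   columns; rows with missing values are dropped and counted.
#' @param outcome Name of the outcome column.
#' @param group Name of the group column.
#' @param covariates Covariates to include (subset of `c("age", "sex")`).
#' @return A `group_glm` list: `f`, `df1`, `df2`, `p`, `eta_p2`, `emm`
#'   (group, emmean, se), `contrasts` (contrast, estimate, t, p),
#'   `n_used`, `n_dropped`, and the fitted `lm` object.
#' @export
fit_group_glm <- function(data, outcome, group = "group",
                          covariates = c("age", "sex")) {
  stopifnot(outcome %in% names(data), group %in% names(data))
  covariates <- intersect(covariates, names(data))
  keep <- complete.cases(data[, c(outcome, group, covariates),
                              drop = FALSE])
  n_dropped <- sum(!keep)
  dat <- data[keep, , drop = FALSE]
  dat$.group <- factor(dat[[group]])
  if (nlevels(dat$.group) < 2) stop("need at least 2 groups")
  if (any(table(dat$.group) < 3))
    stop("need at least 3 observations per group")

  cc <- code_covariates(dat, covariates)
  dat <- cc$data
  rhs <- paste(c(".group", cc$terms), collapse = " + ")
  fml <- as.formula(paste0("`", outcome, "` ~ ", rhs))
  fit <- lm(fml, data = dat, contrasts = list(.group = "contr.sum"))

  X <- model.matrix(fit)
  if (qr(X)$rank < ncol(X)) {
    al <- alias(fit)
    bad <- if (!is.null(al$Complete)) rownames(al$Complete) else "unknown"
    stop("rank-deficient design; aliased column(s): ",
         paste(bad, collapse = ", "))
  }

  rhs_red <- if (length(cc$terms)) paste(cc$terms, collapse = " + ")
             else "1"
  fit0 <- lm(as.formula(paste0("`", outcome, "` ~ ", rhs_red)), data = dat)
  an <- anova(fit0, fit)
  ss_group <- an$`Sum of Sq`[2]
  ss_res <- an$RSS[2]
  fstat <- an$F[2]
  df1 <- an$Df[2]
  df2 <- an$Res.Df[2]
  pval <- an$`Pr(>F)`[2]
  eta_p2 <- ss_group / (ss_group + ss_res)

  em <- emmeans::emmeans(fit, ".group")
  emdf <- as.data.frame(em)
  emm <- data.frame(group = as.character(emdf$.group),
                    emmean = emdf$emmean, se = emdf$SE)
  ctr <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                         adjust = "none"))
  contrasts <- data.frame(contrast = as.character(ctr$contrast),
                          estimate = ctr$estimate, se = ctr$SE,
                          t = ctr$t.ratio, df = ctr$df, p = ctr$p.value)

  structure(list(outcome = outcome, f = fstat, df1 = df1, df2 = df2,
                 p = pval, eta_p2 = eta_p2, emm = emm,
                 contrasts = contrasts, n_used = nrow(dat),
                 n_dropped = n_dropped, fit = fit),
            class = "group_glm")
}

#' @export
print.group_glm <- function(x, ...) {
  cat(sprintf("Group GLM for '%s': F(%d, %d) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
              x$outcome, x$df1, x$df2, x$f, x$p, x$eta_p2))
  cat(sprintf("(n = %d used, %d dropped; no multiple-testing correction)\n",
              x$n_used, x$n_dropped))
  cat("Estimated marginal means:\n")
  print(x$emm, row.names = FALSE)
  cat("Pairwise contrasts (unadjusted):\n")
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Group GLMs across several fitted parameters
#'
#' Runs [fit_group_glm()] for each outcome column and assembles a compact
#' summary table. No multiple-testing correction is applied across the
#' parameter-wise models.
#'
#' @param data Data frame (e.g. [fit_cohort()] merged with demographics).
#' @param outcomes Character vector of outcome column names.
#' @inheritParams fit_group_glm
#' @return A `group_glm_table`: list of `group_glm` results plus a
#'   `summary` data frame (outcome, F, dfs, p, partial eta^2).
#' @export
group_parameter_tests <- function(data, outcomes, group = "group",
                                  covariates = c("age", "sex")) {
  fits <- lapply(setNames(outcomes, outcomes), function(y)
    fit_group_glm(data, y, group = group, covariates = covariates))
  summary <- do.call(rbind, lapply(fits, function(f)
    data.frame(outcome = f$outcome, f = f$f, df1 = f$df1, df2 = f$df2,
               p = f$p, eta_p2 = f$eta_p2)))
  rownames(summary) <- NULL
  structure(list(fits = fits, summary = summary),
            class = "group_glm_table")
}

#' @export
print.group_glm_table <- function(x, ...) {
  cat("Parameter-wise group GLMs (sum-coded group, age + sex covariates;",
      "uncorrected p):\n")
  print(transform(x$summary, f = round(f, 3), p = signif(p, 3),
                  eta_p2 = round(eta_p2, 3)), row.names = FALSE)
  invisible(x)
}

#' Precision-weighted Bayesian group GLM with reduced-model search
#'
#' A parametric-empirical-Bayes style second level: each participant's
#' first-level posterior mean is regressed on the design, weighted by the
#' first-level posterior precision plus a group-level residual variance
#' estimated by evidence maximisation on the full model. All subsets of
#' the non-intercept effects (exhaustive up to 4 effects, greedy backward
#' elimination beyond) are scored by the closed-form Gaussian log
#' evidence; effects retained in the winning reduced model get a posterior
#' probability of deviating from zero (probability mass on the sign of the
#' posterior mean), reported against the 0.75 / 0.95 / 0.99 evidence
#' bands.
#'
#' @param y Vector of first-level posterior means (one per participant).
#' @param X Design matrix with an `(Intercept)` column plus effect
#'   columns (e.g. sum-coded group, centred age, coded sex).
#' @param s2 Vector of first-level posterior variances (> 0).
#' @param prior_var Group-level prior variance per coefficient (default
#'   `1e4`: effectively flat on the scale of parameter effects, so
#'   estimates coincide with weighted least squares and model reduction
#'   penalises free effects decisively).
#' @return A `peb_glm` list: `effects` table (posterior mean/sd, retained
#'   flag, posterior probability, evidence band), `winning` model column
#'   set, `log_evidence` of the winner, model table, estimated residual
#'   variance `resid_var`, and the full (unreduced) model's posterior in
#'   `full_posterior`.
#' @export
peb_bayes_glm <- function(y, X, s2, prior_var = 1e4) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(s2) == n)
  if (any(!is.finite(s2)) || any(s2 <= 0))
    stop("first-level variances must be positive")
  if (!"(Intercept)" %in% colnames(X))
    stop("design must contain an `(Intercept)` column")
  effects <- setdiff(colnames(X), "(Intercept)")

  log_ev <- function(cols, resid_var) {
    Xm <- X[, cols, drop = FALSE]
    V <- s2 + resid_var
    M <- diag(V) + prior_var * tcrossprod(Xm)
    cM <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(cM)) return(-Inf)
    -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(cM))) +
              sum(backsolve(cM, y, transpose = TRUE)^2))
  }
  # Group-level residual variance by evidence maximisation (full model).
  full <- colnames(X)
  opt <- optimize(function(lv) -log_ev(full, exp(lv)),
                  interval = c(log(1e-6), log(1e2)))
  resid_var <- exp(opt$minimum)

  # Candidate reduced models.
  if (length(effects) <= 4) {
    subsets <- lapply(0:(2^length(effects) - 1), function(m) {
      eff <- effects[bitwAnd(m, 2^(seq_along(effects) - 1)) > 0]
      c("(Intercept)", eff)
    })
  } else {
    # Greedy backward elimination from the full model.
    subsets <- list(full)
    current <- full
    repeat {
      cand <- setdiff(current, "(Intercept)")
      if (!length(cand)) break
      evs <- sapply(cand, function(e)
        log_ev(setdiff(current, e), resid_var))
      best <- names(which.max(evs))
      current <- setdiff(current, best)
      subsets <- c(subsets, list(current))
    }
  }
  evs <- sapply(subsets, log_ev, resid_var = resid_var)
  model_table <- data.frame(
    model = sapply(subsets, function(s)
      paste(setdiff(s, "(Intercept)"), collapse = "+")),
    k = lengths(subsets), log_evidence = evs)
  model_table$post_prob <- exp(evs - logsumexp(evs))
  win <- subsets[[which.max(evs)]]

  # Gaussian posterior of a model's coefficients.
  posterior <- function(cols) {
    Xm <- X[, cols, drop = FALSE]
    Vinv <- 1 / (s2 + resid_var)
    prec <- crossprod(Xm, Xm * Vinv) + diag(1 / prior_var, ncol(Xm))
    Sigma <- solve(prec)
    mu <- drop(Sigma %*% crossprod(Xm, y * Vinv))
    names(mu) <- cols
    list(mu = mu, Sigma = Sigma)
  }
  pw <- posterior(win)
  mu <- pw$mu
  Sigma <- pw$Sigma
  pf <- posterior(full)

  band <- function(p) {
    if (!is.finite(p)) return("")
    if (p > 0.99) "very strong" else if (p > 0.95) "strong"
    else if (p > 0.75) "moderate" else "weak"
  }
  eff_rows <- lapply(effects, function(e) {
    retained <- e %in% win
    if (retained) {
      m <- mu[[e]]
      sdv <- sqrt(Sigma[match(e, win), match(e, win)])
      pp <- pnorm(abs(m) / sdv)
    } else {
      m <- 0
      sdv <- 0
      pp <- NA_real_
    }
    data.frame(effect = e, retained = retained, post_mean = m,
               post_sd = sdv, post_prob = pp, evidence = band(pp),
               stringsAsFactors = FALSE)
  })
  structure(list(effects = do.call(rbind, eff_rows),
                 winning = win,
                 log_evidence = max(evs),
                 models = model_table[order(-model_table$log_evidence), ],
                 resid_var = resid_var,
                 intercept = mu[["(Intercept)"]],
                 full_posterior = list(mean = pf$mu,
                                       sd = sqrt(diag(pf$Sigma))),
                 prior_var = prior_var, n = n),
            class = "peb_glm")
}

#' @export
print.peb_glm <- function(x, ...) {
  cat(sprintf(
    "PEB-style Bayesian GLM (n = %d, residual var %.4f, flat-ish prior var %.3g)\n",
    x$n, x$resid_var, x$prior_var))
  cat("Winning reduced model:",
      paste(setdiff(x$winning, "(Intercept)"), collapse = " + ") %||% "",
      "\n")
  print(transform(x$effects, post_mean = round(post_mean, 4),
                  post_sd = round(post_sd, 4),
                  post_prob = round(post_prob, 4)), row.names = FALSE)
  invisible(x)
}

#' PEB-style analyses across fitted parameters
#'
#' Builds, for each transformed-space parameter estimate, the second-level
#' design (intercept, sum-coded group effects, centred age, coded sex) and
#' runs [peb_bayes_glm()] with the per-participant first-level variances.
#'
#' @param data Data frame from [fit_cohort()] (with `*_t` and `*_var`
#'   columns) merged with `group`, `age`, `sex`.
#' @param params Parameter base names (e.g. `c("omega", "eta_loss")`).
#' @param group,covariates As in [fit_group_glm()].
#' @return Named list of `peb_glm` results.
#' @export
peb_parameter_tests <- function(data, params, group = "group",
                                covariates = c("age", "sex")) {
  dat <- data
  dat$.group <- factor(dat[[group]])
  cc <- code_covariates(dat, covariates)
  dat <- cc$data
  Xg <- model.matrix(~.group, dat,
                     contrasts.arg = list(.group = "contr.sum"))
  colnames(Xg) <- c("(Intercept)",
                    paste0("group_", head(levels(dat$.group), -1)))
  X <- cbind(Xg, as.matrix(dat[, cc$terms, drop = FALSE]))
  lapply(setNames(params, params), function(pm) {
    y <- dat[[paste0(pm, "_t")]]
    s2 <- dat[[paste0(pm, "_var")]]
    if (is.null(s2)) stop("missing first-level variances for ", pm)
    ok <- is.finite(y) & is.finite(s2) & s2 > 0
    peb_bayes_glm(y[ok], X[ok, , drop = FALSE], s2[ok])
  })
}
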