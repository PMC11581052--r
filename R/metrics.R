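# Model-free behavioural metrics, iterative Grubbs outlier screening, and
# reaction-time coupling with model-derived confidence measures.

#' Model-free summary of one participant's task behaviour
#'
#' Win-stay is the proportion of trials on which the same option was chosen
#' again after a win; lose-shift the proportion on which a different option
#' was chosen after a loss. Only within-block successors count: pairs that
#' straddle a block boundary are excluded because contingencies reset.
#'
#' @param trials Trial data frame for one participant (see
#'   [validate_trials()]).
#' @return A `model_free_summary` data frame row: `total_wins`, `mean_rt`
#'   (NA if no valid reaction times), `win_stay`, `lose_shift`
#'   (NA when no valid antecedent trials exist), and the pair counts.
#' @export
model_free_summary <- function(trials) {
  trials <- validate_trials(trials)
  n <- nrow(trials)
  same_block <- trials$block[-n] == trials$block[-1]
  stay <- trials$choice[-n] == trials$choice[-1]
  win_t <- trials$outcome[-n] == "win"

  ws_n <- sum(same_block & win_t)
  ls_n <- sum(same_block & !win_t)
  win_stay <- if (ws_n > 0) sum(same_block & win_t & stay) / ws_n
              else NA_real_
  lose_shift <- if (ls_n > 0) sum(same_block & !win_t & !stay) / ls_n
                else NA_real_
  mean_rt <- if ("rt_ms" %in% names(trials) && any(!is.na(trials$rt_ms)))
    mean(trials$rt_ms, na.rm = TRUE) else NA_real_

  out <- data.frame(total_wins = sum(trials$outcome == "win"),
                    mean_rt = mean_rt,
                    win_stay = win_stay, lose_shift = lose_shift,
                    n_win_pairs = ws_n, n_loss_pairs = ls_n)
  class(out) <- c("model_free_summary", "data.frame")
  out
}

#' Model-free summaries for a whole cohort
#'
#' @param trials Cohort trial data frame with `participant_id` (and
#'   optionally `group`).
#' @return Data frame with one row per participant.
#' @export
model_free_table <- function(trials) {
  stopifnot("participant_id" %in% names(trials))
  parts <- split(trials, trials$participant_id)
  rows <- lapply(names(parts), function(id) {
    s <- model_free_summary(parts[[id]])
    s$participant_id <- id
    if ("group" %in% names(parts[[id]])) s$group <- parts[[id]]$group[1]
    s
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Iterative Grubbs outlier screen
#'
#' Repeatedly tests the single most extreme value against the two-sided
#' Grubbs critical value
#' `G_crit = ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(alpha / (2 n), n - 2, lower.tail = FALSE)`, removing it while
#' significant and stopping at the first non-rejection.
#'
#' @param x Numeric vector (NA allowed; never flagged).
#' @param alpha Per-iteration significance threshold (default 0.01).
#' @return Integer vector of flagged positions in `x` (possibly empty), in
#'   removal order.
#' @export
grubbs_iterative <- function(x, alpha = 0.01) {
  idx <- which(!is.na(x))
  if (length(idx) < 3) stop("Grubbs test needs at least 3 non-missing values")
  flagged <- integer(0)
  repeat {
    if (length(idx) < 3) break
    v <- x[idx]
    s <- sd(v)
    if (s == 0) break
    dev <- abs(v - mean(v))
    i_max <- which.max(dev)
    n <- length(v)
    tq <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
    g_crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
    if (dev[i_max] / s <= g_crit) break
    flagged <- c(flagged, idx[i_max])
    idx <- idx[-i_max]
  }
  flagged
}

#' Reaction-time coupling with model-derived confidence
#'
#' Pearson correlations, within one participant, between reaction time and
#' (i) choice uncertainty (policy entropy) on the same trial and (ii) the
#' negated signed belief update on the previous trial (sign flipped so
#' that larger values mean bigger confidence-reducing updates, predicted
#' to slow the next response). First trials of blocks are excluded from
#' the update pairing.
#'
#' @param trials Trial data frame with an `rt_ms` column.
#' @param diagnostics Aligned diagnostics (same ordering) with `entropy`
#'   and `belief_update` columns, e.g. from [trial_diagnostics()].
#' @param min_pairs Minimum usable pairs (default 10).
#' @return A `coupling_result` data frame row: `r_rt_entropy`,
#'   `r_rt_update` (NA when a variable has zero variance), `n_entropy`,
#'   `n_update`.
#' @export
rt_coupling <- function(trials, diagnostics, min_pairs = 10) {
  trials <- validate_trials(trials)
  if (nrow(trials) != nrow(diagnostics))
    stop("`diagnostics` must align with `trials`")
  if (!"rt_ms" %in% names(trials)) stop("`trials` must contain `rt_ms`")
  rt <- trials$rt_ms

  safe_cor <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < min_pairs) return(list(r = NA_real_, n = sum(ok)))
    if (sd(a[ok]) == 0 || sd(b[ok]) == 0)
      return(list(r = NA_real_, n = sum(ok)))
    list(r = cor(a[ok], b[ok]), n = sum(ok))
  }

  ce <- safe_cor(rt, diagnostics$entropy)

  n <- nrow(trials)
  prev_same_block <- c(FALSE, trials$block[-1] == trials$block[-n])
  upd_prev <- c(NA_real_, -diagnostics$belief_update[-n])
  upd_prev[!prev_same_block] <- NA_real_
  cu <- safe_cor(rt, upd_prev)

  out <- data.frame(r_rt_entropy = ce$r, r_rt_update = cu$r,
                    n_entropy = ce$n, n_update = cu$n)
  class(out) <- c("coupling_result", "data.frame")
  out
}

#' Reaction-time coupling for a whole cohort
#'
#' @param trials Cohort trial data frame with `participant_id`.
#' @param diagnostics Cohort diagnostics with `participant_id`, aligned
#'   within each participant.
#' @param min_pairs Passed to [rt_coupling()].
#' @return Data frame, one row per participant (plus `group` if present).
#' @export
coupling_table <- function(trials, diagnostics, min_pairs = 10) {
  stopifnot("participant_id" %in% names(trials),
            "participant_id" %in% names(diagnostics))
  parts <- split(trials, trials$participant_id)
  diags <- split(diagnostics, diagnostics$participant_id)
  rows <- lapply(names(parts), function(id) {
    r <- rt_coupling(parts[[id]], diags[[id]], min_pairs)
    r$participant_id <- id
    if ("group" %in% names(parts[[id]])) r$group <- parts[[id]]$group[1]
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group-level tests on reaction-time coupling coefficients
#'
#' One-sample t-tests of each per-participant correlation measure against
#' zero, plus (when group labels and covariates are supplied) a
#' sum-coded group GLM with estimated-marginal-mean contrasts via
#' [fit_group_glm()].
#'
#' @param coupling Data frame from [coupling_table()].
#' @param covariates Optional data frame with `participant_id`, `group`,
#'   `age`, `sex` for the group GLM.
#' @return List with `t_tests` (one row per measure: mean, sd, t, df, p)
#'   and `group_glm` (list per measure, or NULL).
#' @export
coupling_group_tests <- function(coupling, covariates = NULL) {
  measures <- c("r_rt_entropy", "r_rt_update")
  tt <- lapply(measures, function(m) {
    v <- coupling[[m]]
    v <- v[is.finite(v)]
    if (length(v) < 2 || sd(v) == 0) {
      # zero-variance guard: a degenerate sample of identical r values is
      # reported as t = 0, p = 1 when centred on zero, else as a limiting
      # rejection
      mu <- mean(v)
      return(data.frame(measure = m, mean = mu, sd = sd(v),
                        t = if (isTRUE(all.equal(mu, 0))) 0
                            else sign(mu) * Inf,
                        df = length(v) - 1,
                        p = if (isTRUE(all.equal(mu, 0))) 1 else 0,
                        n = length(v)))
    }
    ht <- t.test(v, mu = 0)
    data.frame(measure = m, mean = mean(v), sd = sd(v),
               t = unname(ht$statistic), df = unname(ht$parameter),
               p = ht$p.value, n = length(v))
  })
  t_tests <- do.call(rbind, tt)

  group_glm <- NULL
  if (!is.null(covariates)) {
    dat <- merge(coupling, covariates, by = "participant_id",
                 suffixes = c("", ".cov"))
    if ("group.cov" %in% names(dat)) dat$group <- dat$group.cov
    counts <- table(dat$group[is.finite(dat$r_rt_entropy)])
    if (any(counts < 2)) {
      message("group GLM skipped: a group has fewer than 2 participants")
    } else {
      group_glm <- lapply(setNames(measures, measures), function(m)
        fit_group_glm(dat, outcome = m))
    }
  }
  list(t_tests = t_tests, group_glm = group_glm)
}
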