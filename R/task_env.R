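# Task environment: block schedules of reward probabilities and outcome
# sampling for the three-armed bandit.

#' Default menu of reward-probability triples
#'
#' Four triples, each with a clearly best, a middle and a worst option,
#' spanning easy and hard discriminations and richer and poorer blocks.
#' The triple assigned to each block is drawn from this menu with its
#' option order permuted, so the identity (and quality) of the best arm
#' must be re-learned every block. Varying the contingencies across blocks
#' matters statistically: with a single repeated triple, a change in
#' learning rate can be mimicked almost exactly by a change in softmax
#' temperature, whereas heterogeneous blocks break that degeneracy and
#' make the model parameters identifiable.
#'
#' @return A list of numeric length-3 probability vectors.
#' @export
default_prob_menu <- function() {
  list(c(0.9, 0.6, 0.3), c(0.8, 0.5, 0.2),
       c(0.7, 0.4, 0.1), c(0.6, 0.35, 0.15))
}

#' Build a block schedule for the three-armed bandit task
#'
#' Assigns one reward-probability triple (drawn from `prob_menu`, with the
#' option order randomised) to each block. Probabilities are fixed within a
#' block and change between blocks.
#'
#' @param n_blocks Number of blocks (default 20).
#' @param n_trials Number of trials per block (default 16).
#' @param prob_menu List of numeric length-3 vectors of win probabilities.
#' @param seed Optional integer seed; the schedule is deterministic given it.
#' @return A `block_schedule`: list with `n_blocks`, `n_trials_per_block`
#'   and a `n_blocks x 3` matrix `probs` of per-option win probabilities.
#' @examples
#' sched <- make_schedule(seed = 7)
#' dim(sched$probs)
#' @export
make_schedule <- function(n_blocks = 20, n_trials = 16,
                          prob_menu = default_prob_menu(), seed = NULL) {
  if (!is.numeric(n_blocks) || n_blocks < 1 || n_blocks != round(n_blocks))
    stop("`n_blocks` must be a positive integer")
  if (!is.numeric(n_trials) || n_trials < 1 || n_trials != round(n_trials))
    stop("`n_trials` must be a positive integer")
  if (!is.list(prob_menu) || length(prob_menu) == 0)
    stop("`prob_menu` must be a non-empty list of probability triples")
  for (tr in prob_menu) {
    if (!is.numeric(tr) || length(tr) != 3L || any(!is.finite(tr)) ||
        any(tr < 0) || any(tr > 1))
      stop("each menu entry must be 3 probabilities in [0, 1]")
  }
  probs <- with_seed(seed, {
    m <- matrix(NA_real_, nrow = n_blocks, ncol = 3)
    for (b in seq_len(n_blocks)) {
      triple <- prob_menu[[sample.int(length(prob_menu), 1L)]]
      m[b, ] <- triple[sample.int(3L)]
    }
    m
  })
  colnames(probs) <- paste0("option", 1:3)
  structure(list(n_blocks = as.integer(n_blocks),
                 n_trials_per_block = as.integer(n_trials),
                 probs = probs),
            class = "block_schedule")
}

#' @export
print.block_schedule <- function(x, ...) {
  cat(sprintf("Three-armed bandit schedule: %d blocks x %d trials\n",
              x$n_blocks, x$n_trials_per_block))
  print(head(x$probs, 5))
  if (x$n_blocks > 5) cat(sprintf("... (%d more blocks)\n", x$n_blocks - 5))
  invisible(x)
}

#' Sample a win/loss outcome for a choice
#'
#' Bernoulli draw with the scheduled win probability of the chosen option
#' in the given block, using the current RNG stream.
#'
#' @param schedule A `block_schedule`.
#' @param block Block index (1-based).
#' @param choice Option index in 1..3.
#' @return `"win"` or `"loss"`.
#' @export
sample_outcome <- function(schedule, block, choice) {
  stopifnot(inherits(schedule, "block_schedule"))
  if (!is.numeric(block) || length(block) != 1L || block < 1 ||
      block > schedule$n_blocks)
    stop("`block` out of range")
  if (!is.numeric(choice) || length(choice) != 1L || !(choice %in% 1:3))
    stop("`choice` must be 1, 2 or 3")
  if (runif(1) < schedule$probs[block, choice]) "win" else "loss"
}

#' Write / read a schedule as JSON
#'
#' @param schedule A `block_schedule`.
#' @param path File path.
#' @return `read_schedule` returns a `block_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "block_schedule"))
  obj <- list(n_blocks = schedule$n_blocks,
              n_trials_per_block = schedule$n_trials_per_block,
              probs = unname(schedule$probs))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  probs <- matrix(as.numeric(as.matrix(obj$probs)), ncol = 3)
  colnames(probs) <- paste0("option", 1:3)
  structure(list(n_blocks = as.integer(obj$n_blocks),
                 n_trials_per_block = as.integer(obj$n_trials_per_block),
                 probs = probs),
            class = "block_schedule")
}

#' Validate a per-participant trial table
#'
#' Checks ordering and uniqueness of (block, trial), choice codes,
#' outcome codes and (optional) positive reaction times.
#'
#' @param trials Data frame with columns `block`, `trial`, `choice`
#'   (1..3), `outcome` (`"win"`/`"loss"`), and optionally `rt_ms`.
#' @return The validated data frame (invisibly), ordered by block, trial.
#' @export
validate_trials <- function(trials) {
  need <- c("block", "trial", "choice", "outcome")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table is missing columns: ", paste(miss, collapse = ", "))
  trials <- trials[order(trials$block, trials$trial), , drop = FALSE]
  key <- paste(trials$block, trials$trial)
  if (anyDuplicated(key))
    stop("duplicated (block, trial) pairs in trial table")
  if (!all(trials$choice %in% 1:3))
    stop("`choice` must be in {1, 2, 3}")
  if (!all(trials$outcome %in% c("win", "loss")))
    stop('`outcome` must be "win" or "loss"')
  if ("rt_ms" %in% names(trials)) {
    bad <- !is.na(trials$rt_ms) & trials$rt_ms <= 0
    if (any(bad)) stop("`rt_ms` must be positive where present")
  }
  invisible(trials)
}

#' Write / read cohort trial data as CSV
#'
#' Columns: `participant_id`, `group`, `block`, `trial`, `choice` (1-based),
#' `outcome` (`win`/`loss`), `rt_ms` (empty when missing).
#'
#' @param trials Data frame of trials (one or many participants).
#' @param path File path.
#' @return `read_trials` returns the trial data frame.
#' @export
write_trials <- function(trials, path) {
  cols <- intersect(c("participant_id", "group", "block", "trial",
                      "choice", "outcome", "rt_ms"), names(trials))
  write.csv(trials[, cols, drop = FALSE], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("rt_ms" %in% names(df)) df$rt_ms <- as.numeric(df$rt_ms)
  df
}

# Internal: 0-based integer encoding for the C++ filters.
encode_trials <- function(trials) {
  trials <- validate_trials(trials)
  list(block = as.integer(trials$block),
       choice = as.integer(trials$choice) - 1L,
       outcome = as.integer(trials$outcome == "win"),
       trials = trials)
}
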