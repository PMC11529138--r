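#' Define a stimulus pair of the probabilistic selection task
#'
#' A pair couples a "better" symbol, reinforced with probability
#' `p_correct_better`, to a "worse" symbol reinforced with the complementary
#' probability. In the standard task the pairs are AB (80/20), CD (70/30)
#' and EF (60/40).
#'
#' @param label Pair identifier, e.g. `"AB"`.
#' @param better_symbol,worse_symbol Distinct symbol identifiers.
#' @param p_correct_better Probability in `[0.5, 1]` that choosing the better
#'   symbol yields positive feedback.
#' @return An object of class `"pst_pair"`.
#' @export
pst_pair <- function(label, better_symbol, worse_symbol, p_correct_better) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.numeric(p_correct_better) || length(p_correct_better) != 1L ||
      p_correct_better < 0.5 || p_correct_better > 1)
    stop("p_correct_better must be a single value in [0.5, 1]")
  if (identical(better_symbol, worse_symbol))
    stop("better_symbol and worse_symbol must differ")
  structure(list(label = label,
                 better_symbol = better_symbol,
                 worse_symbol = worse_symbol,
                 p_correct_better = p_correct_better),
            class = "pst_pair")
}

#' Define a probabilistic selection task
#'
#' @param pairs List of [pst_pair()] objects; symbols must be unique across
#'   pairs.
#' @param trials_per_pair_per_block Presentations of each pair within a block.
#' @param criteria Named numeric vector, pair label -> minimum block accuracy
#'   (proportion of optimal choices) required by the stopping rule.
#' @param max_blocks Maximum number of learning blocks before the session is
#'   abandoned (and the simulated participant flagged for exclusion).
#' @param metadata Optional list of timing/display constants that do not enter
#'   the simulation (e.g. feedback duration).
#' @return An object of class `"pst_task"` with derived field `block_size =
#'   trials_per_pair_per_block * length(pairs)`.
#' @export
pst_task <- function(pairs, trials_per_pair_per_block, criteria, max_blocks,
                     metadata = list()) {
  stopifnot(is.list(pairs), length(pairs) >= 1L)
  if (!all(vapply(pairs, inherits, logical(1), "pst_pair")))
    stop("all elements of 'pairs' must be pst_pair objects")
  labels <- vapply(pairs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("pair labels must be unique")
  symbols <- unlist(lapply(pairs, function(p) c(p$better_symbol, p$worse_symbol)))
  if (anyDuplicated(symbols)) stop("symbols must be unique across pairs")
  if (!is.numeric(criteria) || is.null(names(criteria)))
    stop("criteria must be a named numeric vector")
  if (!setequal(names(criteria), labels))
    stop("criteria must have exactly one entry per pair label")
  if (any(criteria < 0 | criteria > 1)) stop("criteria must lie in [0, 1]")
  stopifnot(trials_per_pair_per_block >= 1L, max_blocks >= 1L)
  names(pairs) <- labels
  structure(list(pairs = pairs,
                 trials_per_pair_per_block = as.integer(trials_per_pair_per_block),
                 block_size = as.integer(trials_per_pair_per_block) * length(pairs),
                 criteria = criteria[labels],
                 max_blocks = as.integer(max_blocks),
                 metadata = metadata),
            class = "pst_task")
}

#' The standard probabilistic selection task
#'
#' Three Hiragana-symbol pairs reinforced at 80/20 (AB), 70/30 (CD) and
#' 60/40 (EF); blocks of 60 trials with each pair shown 20 times; stopping
#' criteria of 60% (AB), 55% (CD) and 50% (EF) optimal choices in the
#' just-completed block; at most six blocks (360 trials).
#'
#' @return A `"pst_task"` object.
#' @examples
#' task <- make_standard_task()
#' task$pairs$AB$p_correct_better  # 0.8
#' @export
make_standard_task <- function() {
  pst_task(
    pairs = list(pst_pair("AB", "A", "B", 0.8),
                 pst_pair("CD", "C", "D", 0.7),
                 pst_pair("EF", "E", "F", 0.6)),
    trials_per_pair_per_block = 20L,
    criteria = c(AB = 0.60, CD = 0.55, EF = 0.50),
    max_blocks = 6L,
    metadata = list(feedback_ms = 1000, blank_ms = 500)
  )
}

#' @export
print.pst_task <- function(x, ...) {
  cat("Probabilistic selection task:", length(x$pairs), "pairs,",
      x$block_size, "trials/block, max", x$max_blocks, "blocks\n")
  for (p in x$pairs)
    cat(sprintf("  %s: %s (p = %.2f) vs %s; criterion %.2f\n", p$label,
                p$better_symbol, p$p_correct_better, p$worse_symbol,
                x$criteria[[p$label]]))
  invisible(x)
}

#' Draw a randomised block order
#'
#' Each pair appears exactly `trials_per_pair_per_block` times in a uniformly
#' shuffled order, and the better symbol sits on the left with probability
#' one half, independently per trial. Uses the current R random stream.
#'
#' @param config A `"pst_task"` object.
#' @return A data frame with columns `pair`, `left`, `right`.
#' @export
generate_block_order <- function(config) {
  if (!inherits(config, "pst_task")) stop("config must be a pst_task object")
  labels <- rep(names(config$pairs), each = config$trials_per_pair_per_block)
  labels <- sample(labels)
  better_left <- stats::runif(length(labels)) < 0.5
  bet <- vapply(config$pairs, `[[`, character(1), "better_symbol")[labels]
  wor <- vapply(config$pairs, `[[`, character(1), "worse_symbol")[labels]
  data.frame(pair = labels,
             left = ifelse(better_left, bet, wor),
             right = ifelse(better_left, wor, bet),
             stringsAsFactors = FALSE)
}

#' Sample probabilistic feedback for a choice
#'
#' @param pair A `"pst_pair"`.
#' @param chose_better Logical; was the pair's better symbol chosen?
#' @param n Number of independent draws.
#' @return Integer vector of rewards in `{0, 1}`.
#' @export
sample_feedback <- function(pair, chose_better, n = 1L) {
  stopifnot(inherits(pair, "pst_pair"), is.logical(chose_better))
  p <- if (chose_better) pair$p_correct_better else 1 - pair$p_correct_better
  as.integer(stats::runif(n) < p)
}

#' Per-pair accuracy of one completed block
#'
#' Accuracy is the proportion of trials on which the pair's better symbol was
#' chosen (not the proportion of positive feedback).
#'
#' @param trials Data frame of one block's trials with columns `pair` and
#'   `chose_optimal`.
#' @param config A `"pst_task"`; every configured pair must be present.
#' @return Named numeric vector, pair label -> accuracy.
#' @export
block_accuracies <- function(trials, config) {
  stopifnot(inherits(config, "pst_task"))
  labels <- names(config$pairs)
  if (!all(labels %in% trials$pair))
    stop("block is missing trials for pair(s): ",
         paste(setdiff(labels, unique(trials$pair)), collapse = ", "))
  vapply(labels, function(l) mean(trials$chose_optimal[trials$pair == l]),
         numeric(1))
}

#' Evaluate the stopping rule
#'
#' TRUE iff every pair's block accuracy meets or exceeds ("or above",
#' inclusive) its criterion.
#'
#' @param accuracies Named numeric vector from [block_accuracies()].
#' @param config A `"pst_task"`.
#' @return Logical scalar.
#' @export
criteria_met <- function(accuracies, config) {
  stopifnot(inherits(config, "pst_task"))
  labels <- names(config$pairs)
  if (!all(labels %in% names(accuracies)))
    stop("accuracies missing pair(s): ",
         paste(setdiff(labels, names(accuracies)), collapse = ", "))
  all(accuracies[labels] >= config$criteria[labels])
}

#' Run a full task session for an agent
#'
#' Presents whole blocks; after each completed block evaluates the stopping
#' criteria on that block alone, and stops when they are met or when
#' `max_blocks` is exhausted. The agent is a list with an `act(pair, left,
#' right)` function returning `list(chosen =, rt =)` and an optional
#' `learn(chosen, reward)` hook called after feedback (see [agent_rlddm()]).
#'
#' @param agent Agent object (see Details).
#' @param config A `"pst_task"`.
#' @param subject_id,condition Labels copied into the trial records.
#' @return A list of class `"pst_session"` with elements `trials` (data frame,
#'   one row per trial), `terminated_by_criteria`, `blocks_completed`, and
#'   `met_criteria` (per-block logical history).
#' @export
run_session <- function(agent, config, subject_id = "s1", condition = "none") {
  stopifnot(inherits(config, "pst_task"), is.list(agent), is.function(agent$act))
  labels <- names(config$pairs)
  blocks <- list()
  met_hist <- logical(0)
  encounter <- stats::setNames(integer(length(labels)), labels)
  trial_no <- 0L
  for (b in seq_len(config$max_blocks)) {
    order <- generate_block_order(config)
    n <- nrow(order)
    rec <- data.frame(subject = subject_id, condition = condition,
                      block = b, trial = integer(n), pair_encounter = integer(n),
                      pair = order$pair, left = order$left, right = order$right,
                      chosen = character(n), chose_optimal = logical(n),
                      feedback = integer(n), rt = numeric(n),
                      stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      pr <- config$pairs[[order$pair[i]]]
      res <- agent$act(order$pair[i], order$left[i], order$right[i])
      if (!res$chosen %in% c(order$left[i], order$right[i]))
        stop("protocol error: agent chose '", res$chosen,
             "', not one of the presented symbols")
      if (!is.numeric(res$rt) || res$rt <= 0)
        stop("protocol error: agent returned non-positive rt")
      chose_better <- identical(res$chosen, pr$better_symbol)
      reward <- sample_feedback(pr, chose_better)
      if (is.function(agent$learn)) agent$learn(res$chosen, reward)
      trial_no <- trial_no + 1L
      encounter[order$pair[i]] <- encounter[order$pair[i]] + 1L
      rec$trial[i] <- trial_no
      rec$pair_encounter[i] <- encounter[order$pair[i]]
      rec$chosen[i] <- res$chosen
      rec$chose_optimal[i] <- chose_better
      rec$feedback[i] <- reward
      rec$rt[i] <- res$rt
    }
    blocks[[b]] <- rec
    met <- criteria_met(block_accuracies(rec, config), config)
    met_hist <- c(met_hist, met)
    if (met) break
  }
  trials <- do.call(rbind, blocks)
  rownames(trials) <- NULL
  structure(list(trials = trials,
                 terminated_by_criteria = met_hist[length(met_hist)],
                 blocks_completed = length(met_hist),
                 met_criteria = met_hist),
            class = "pst_session")
}

#' @export
print.pst_session <- function(x, ...) {
  cat("PST session:", x$blocks_completed, "block(s),", nrow(x$trials),
      "trials;", if (x$terminated_by_criteria) "criteria met" else
        "criteria not met (candidate for exclusion)", "\n")
  invisible(x)
}

#' Reference agents
#'
#' `agent_optimal()` always chooses the pair's better symbol;
#' `agent_random()` chooses uniformly. Both respond with i.i.d. lognormal
#' response times and do not learn. Useful as degenerate baselines for the
#' session runner and the behavioural summaries.
#'
#' @param task A `"pst_task"` (used to look up the better symbol).
#' @param rt_meanlog,rt_sdlog Lognormal response-time parameters (seconds).
#' @return An agent list with an `act` function.
#' @export
agent_optimal <- function(task, rt_meanlog = log(0.8), rt_sdlog = 0.2) {
  list(act = function(pair, left, right) {
    list(chosen = task$pairs[[pair]]$better_symbol,
         rt = stats::rlnorm(1, rt_meanlog, rt_sdlog))
  })
}

#' @rdname agent_optimal
#' @export
agent_random <- function(task, rt_meanlog = log(0.8), rt_sdlog = 0.2) {
  list(act = function(pair, left, right) {
    list(chosen = if (stats::runif(1) < 0.5) left else right,
         rt = stats::rlnorm(1, rt_meanlog, rt_sdlog))
  })
}
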