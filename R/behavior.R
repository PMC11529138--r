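#' Filter response-time outliers
#'
#' Removes trials with response times strictly faster than `low_ms` or
#' strictly slower than `high_ms` (the boundary values themselves are kept).
#' Defaults follow the conventional 200 / 4,000 ms window for the
#' probabilistic selection task.
#'
#' @param trials Trial data frame with an `rt` column in seconds.
#' @param low_ms,high_ms Cutoffs in milliseconds, `0 < low_ms < high_ms`.
#' @return `list(trials =, removed =, fraction =)`.
#' @export
filter_rt_outliers <- function(trials, low_ms = 200, high_ms = 4000) {
  if (!is.numeric(low_ms) || !is.numeric(high_ms) ||
      low_ms <= 0 || high_ms <= low_ms)
    stop("cutoffs must satisfy 0 < low_ms < high_ms")
  rt_ms <- trials$rt * 1000
  keep <- rt_ms >= low_ms & rt_ms <= high_ms
  list(trials = trials[keep, , drop = FALSE],
       removed = sum(!keep),
       fraction = mean(!keep))
}

#' Per-subject and per-condition performance summaries
#'
#' Accuracy is the mean of `chose_optimal` per subject; condition summaries
#' are unweighted means (and SDs) of the subject means. Mean response time is
#' summarised the same way.
#'
#' @param trials Filtered trial data frame.
#' @return `list(subjects =, conditions =)` of data frames.
#' @export
performance_summary <- function(trials) {
  split_by <- interaction(trials$subject, drop = TRUE)
  subj <- do.call(rbind, lapply(split(trials, split_by), function(d) {
    data.frame(subject = d$subject[1], condition = d$condition[1],
               n_trials = nrow(d), accuracy = mean(d$chose_optimal),
               mean_rt = mean(d$rt), stringsAsFactors = FALSE)
  }))
  rownames(subj) <- NULL
  empty <- subj$n_trials == 0
  if (any(empty)) {
    warning("excluding ", sum(empty), " subject(s) with zero trials")
    subj <- subj[!empty, , drop = FALSE]
  }
  cond <- do.call(rbind, lapply(split(subj, subj$condition), function(d) {
    data.frame(condition = d$condition[1], n_subjects = nrow(d),
               accuracy_mean = mean(d$accuracy), accuracy_sd = stats::sd(d$accuracy),
               rt_mean = mean(d$mean_rt), rt_sd = stats::sd(d$mean_rt),
               stringsAsFactors = FALSE)
  }))
  rownames(cond) <- NULL
  list(subjects = subj, conditions = cond)
}

#' Trial-by-trial learning curves
#'
#' For every condition x pair x pair-encounter index (1..`first_n`), the
#' proportion of subjects choosing the pair's optimal symbol. "First n
#' responses" counts per-pair encounters, matching analyses that cross trial
#' number with stimulus pair. The long-format output is directly consumable
#' by longitudinal (e.g. GEE) software.
#'
#' @param trials Trial data frame with a `pair_encounter` column.
#' @param first_n Number of encounters to keep per pair (default 30).
#' @return Data frame `condition, pair, encounter, prop_optimal, n_subjects`.
#' @export
learning_curve <- function(trials, first_n = 30) {
  if (!"pair_encounter" %in% names(trials))
    stop("trials must carry a pair_encounter column")
  avail <- max(trials$pair_encounter)
  if (first_n > avail) {
    warning("only ", avail, " encounters available; truncating first_n")
    first_n <- avail
  }
  d <- trials[trials$pair_encounter <= first_n, , drop = FALSE]
  agg <- stats::aggregate(chose_optimal ~ condition + pair + pair_encounter,
                          data = d, FUN = mean)
  nsub <- stats::aggregate(subject ~ condition + pair + pair_encounter,
                           data = d, FUN = function(s) length(unique(s)))
  out <- merge(agg, nsub, by = c("condition", "pair", "pair_encounter"))
  names(out) <- c("condition", "pair", "encounter", "prop_optimal",
                  "n_subjects")
  out <- out[order(out$condition, out$pair, out$encounter), ]
  rownames(out) <- NULL
  out
}

#' Write a learning curve as CSV
#'
#' @param curve Output of [learning_curve()].
#' @param path File path.
#' @export
write_learning_curve <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
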