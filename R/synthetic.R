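# Synthetic two-condition PST studies: subject-level RL-DDM parameters drawn
# from condition-specific group distributions, sessions simulated with the
# learning diffusion agent. Mirrors the hierarchical structure the fitting
# code assumes, so recovery can be validated end to end.

.transform_of <- c(eta = "logit", eta_pos = "logit", eta_neg = "logit",
                   v_scaling = "log", a = "log", t0 = "log")

.to_internal <- function(name, x) {
  if (.transform_of[[name]] == "logit") stats::qlogis(x) else log(x)
}
.from_internal <- function(name, x) {
  if (.transform_of[[name]] == "logit") stats::plogis(x) else exp(x)
}

#' Group-level parameter distribution for one condition
#'
#' Group means are given on the natural scale; between-subject spreads are
#' standard deviations on the sampling scale (logit for learning rates, log
#' for `v_scaling`, `a`, `t0`), matching the hierarchical model fitted by
#' [fit_rlddm()].
#'
#' @param condition Condition label.
#' @param means Named numeric vector of natural-scale group means: either
#'   `eta` or `eta_pos`/`eta_neg`, plus `v_scaling`, `a`, `t0`.
#' @param sds Named numeric vector of transformed-scale spreads (same names).
#' @return An object of class `"condition_params"`.
#' @export
condition_params <- function(condition, means, sds) {
  stopifnot(is.character(condition), length(condition) == 1L)
  if (!setequal(names(means), names(sds)))
    stop("means and sds must share names")
  if (!all(names(means) %in% names(.transform_of)))
    stop("unknown parameter name(s): ",
         paste(setdiff(names(means), names(.transform_of)), collapse = ", "))
  if (any(sds < 0)) stop("spreads must be non-negative")
  rates <- intersect(names(means), c("eta", "eta_pos", "eta_neg"))
  ok <- identical(sort(rates), "eta") ||
    identical(sort(rates), c("eta_neg", "eta_pos"))
  if (!ok) stop("supply either eta, or both eta_pos and eta_neg")
  if (!all(c("v_scaling", "a", "t0") %in% names(means)))
    stop("means must include v_scaling, a and t0")
  mu <- vapply(names(means), function(k) .to_internal(k, means[[k]]),
               numeric(1))
  structure(list(condition = condition, mu = mu,
                 sigma = sds[names(means)],
                 rate_structure = if ("eta" %in% names(means)) "single"
                                  else "dual"),
            class = "condition_params")
}

#' Draw subject-level parameters from a condition distribution
#'
#' Normal draws on the sampling scale, back-transformed; uses the current R
#' random stream.
#'
#' @param cond A `"condition_params"`.
#' @param n Number of subjects.
#' @return A data frame of natural-scale parameters, one row per subject.
#' @export
draw_subject_params <- function(cond, n = 1L) {
  stopifnot(inherits(cond, "condition_params"))
  draws <- vapply(names(cond$mu), function(k)
    .from_internal(k, stats::rnorm(n, cond$mu[[k]], cond$sigma[[k]])),
    numeric(n))
  if (n == 1L) draws <- matrix(draws, nrow = 1,
                               dimnames = list(NULL, names(cond$mu)))
  as.data.frame(draws)
}

#' Configure a synthetic two-condition study
#'
#' @param n_subjects Subjects per condition.
#' @param conditions List of exactly two [condition_params()] objects with a
#'   common rate structure.
#' @param task A `"pst_task"` (default [make_standard_task()]).
#' @param seed Master seed; every generated trial is reproducible from
#'   `(seed, subject index)`.
#' @param dt Diffusion integration step for the simulated agents (seconds).
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(n_subjects, conditions, task = make_standard_task(),
                         seed = 1L, dt = 1e-4) {
  stopifnot(n_subjects >= 1L, is.list(conditions), length(conditions) == 2L)
  if (!all(vapply(conditions, inherits, logical(1), "condition_params")))
    stop("conditions must be condition_params objects")
  rs <- unique(vapply(conditions, `[[`, character(1), "rate_structure"))
  if (length(rs) != 1L)
    stop("both conditions must share a rate structure")
  labels <- vapply(conditions, `[[`, character(1), "condition")
  if (anyDuplicated(labels)) stop("condition labels must be distinct")
  names(conditions) <- labels
  structure(list(n_subjects = as.integer(n_subjects), conditions = conditions,
                 rate_structure = rs, task = task, seed = as.integer(seed),
                 dt = dt),
            class = "study_config")
}

#' Preset study configurations
#'
#' `"null"`: both conditions share the same group distribution (dual rates
#' `eta_pos` 0.15 / `eta_neg` 0.10, `v_scaling` 2.5, `a` 1.6, `t0` 0.35 s) —
#' the no-effect calibration case. `"paper_like"`: control as in `"null"`,
#' while the mindfulness condition has a higher positive-error learning rate
#' (0.30), lower drift scaling (1.8) and higher boundary (2.1), i.e. the
#' qualitative effect directions of brief-meditation studies on this task;
#' effect magnitudes are this package's invented defaults.
#'
#' @param name `"null"` or `"paper_like"`.
#' @param n_subjects Subjects per condition (default 30).
#' @param seed Master seed.
#' @param dt Diffusion integration step (seconds).
#' @return A `"study_config"`.
#' @export
study_preset <- function(name = c("null", "paper_like"), n_subjects = 30L,
                         seed = 1L, dt = 1e-4) {
  name <- match.arg(name)
  sds <- c(eta_pos = 0.4, eta_neg = 0.4, v_scaling = 0.25, a = 0.15,
           t0 = 0.10)
  control_means <- c(eta_pos = 0.15, eta_neg = 0.10, v_scaling = 2.5,
                     a = 1.6, t0 = 0.35)
  mind_means <- if (name == "null") control_means else
    c(eta_pos = 0.30, eta_neg = 0.10, v_scaling = 1.8, a = 2.1, t0 = 0.35)
  study_config(
    n_subjects = n_subjects,
    conditions = list(condition_params("control", control_means, sds),
                      condition_params("mindfulness", mind_means, sds)),
    seed = seed, dt = dt
  )
}

.subject_seed <- function(master, index) {
  as.integer((as.numeric(master) + 7919 * index) %% 2147483629)
}

.params_from_row <- function(row, rate_structure) {
  if (rate_structure == "single")
    agent_params(eta = row$eta, v_scaling = row$v_scaling, a = row$a,
                 t0 = row$t0)
  else
    agent_params(eta_pos = row$eta_pos, eta_neg = row$eta_neg,
                 v_scaling = row$v_scaling, a = row$a, t0 = row$t0)
}

#' Generate a complete synthetic study
#'
#' For each subject: draw RL-DDM parameters from the condition's group
#' distribution, run a full criterion-terminated session with the learning
#' diffusion agent, and record every trial. Subjects that fail the stopping
#' criteria within `max_blocks` are flagged `excluded = TRUE` but kept, so an
#' exclusion rule can be applied downstream as a filter.
#'
#' @param config A `"study_config"`.
#' @return A list of class `"pst_study"`: `trials` (one row per trial),
#'   `truth` (subject, condition, true parameters, `excluded`,
#'   `blocks_completed`, `session_seed`), and `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  trials <- list(); truth <- list(); idx <- 0L
  for (cond in config$conditions) {
    for (i in seq_len(config$n_subjects)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%02d", cond$condition, i)
      seed_i <- .subject_seed(config$seed, idx)
      set.seed(seed_i)
      row <- draw_subject_params(cond, 1L)
      params <- .params_from_row(row, config$rate_structure)
      session_seed <- .subject_seed(seed_i, 104729L)
      set.seed(session_seed)
      sess <- run_session(agent_rlddm(params, config$task, dt = config$dt),
                          config$task, subject_id = sid,
                          condition = cond$condition)
      trials[[idx]] <- sess$trials
      truth[[idx]] <- cbind(
        data.frame(subject = sid, condition = cond$condition,
                   stringsAsFactors = FALSE),
        row,
        data.frame(excluded = !sess$terminated_by_criteria,
                   blocks_completed = sess$blocks_completed,
                   session_seed = session_seed))
    }
  }
  structure(list(trials = do.call(rbind, trials),
                 truth = do.call(rbind, truth),
                 config = config),
            class = "pst_study")
}

#' @export
print.pst_study <- function(x, ...) {
  cat("Synthetic PST study:", nrow(x$truth), "subjects (",
      x$config$n_subjects, "per condition ),", nrow(x$trials), "trials;",
      sum(x$truth$excluded), "flagged for exclusion\n")
  invisible(x)
}

#' Re-simulate one subject's session from stored ground truth
#'
#' Replays the stored session seed with the stored true parameters; the
#' result is identical to the trials originally recorded for that subject.
#'
#' @param study A `"pst_study"`.
#' @param subject Subject identifier from `study$truth`.
#' @return The re-simulated trial data frame.
#' @export
resimulate_subject <- function(study, subject) {
  stopifnot(inherits(study, "pst_study"))
  row <- study$truth[study$truth$subject == subject, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown subject: ", subject)
  params <- .params_from_row(row, study$config$rate_structure)
  set.seed(row$session_seed)
  sess <- run_session(agent_rlddm(params, study$config$task,
                                  dt = study$config$dt),
                      study$config$task, subject_id = subject,
                      condition = row$condition)
  sess$trials
}

#' Write a study to disk
#'
#' Emits the trial CSV (schema of [write_trials()]), a ground-truth CSV and a
#' JSON manifest recording the seed, rate structure and group-level
#' configuration (effect magnitudes in presets are package defaults, not
#' empirical estimates).
#'
#' @param study A `"pst_study"`.
#' @param dir Output directory (created if needed).
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "pst_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trials(study$trials, file.path(dir, "trials.csv"))
  utils::write.csv(study$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- study$config
  manifest <- list(
    seed = cfg$seed, n_subjects_per_condition = cfg$n_subjects,
    rate_structure = cfg$rate_structure, dt = cfg$dt,
    note = "synthetic data; preset effect magnitudes are package defaults",
    conditions = lapply(cfg$conditions, function(cc)
      list(condition = cc$condition, mu_internal = as.list(cc$mu),
           sigma_internal = as.list(cc$sigma)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
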