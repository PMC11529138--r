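#' Read and write trial tables
#'
#' Trial tables are stored as CSV with one row per trial and columns
#' `subject,condition,block,trial,pair_encounter,pair,left,right,chosen,
#' chose_optimal,feedback,rt_ms`. Response times are stored in milliseconds
#' on disk and held in seconds (`rt`) in memory.
#'
#' @param trials In-memory trial data frame (`rt` in seconds).
#' @param path File path.
#' @return `read_trials()` returns the in-memory trial data frame.
#' @export
write_trials <- function(trials, path) {
  out <- trials[c("subject", "condition", "block", "trial", "pair_encounter",
                  "pair", "left", "right", "chosen", "chose_optimal",
                  "feedback")]
  out$rt_ms <- trials$rt * 1000
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "condition", "block", "trial", "pair_encounter", "pair",
            "left", "right", "chosen", "chose_optimal", "feedback", "rt_ms")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("trial CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  x$chose_optimal <- as.logical(x$chose_optimal)
  x$rt <- x$rt_ms / 1000
  x$rt_ms <- NULL
  x
}

#' Read and write task configurations as JSON
#'
#' @param config A `"pst_task"`.
#' @param path File path.
#' @return `read_task_json()` returns a `"pst_task"`.
#' @export
write_task_json <- function(config, path) {
  stopifnot(inherits(config, "pst_task"))
  obj <- list(
    pairs = lapply(unname(config$pairs), function(p)
      list(label = p$label, better_symbol = p$better_symbol,
           worse_symbol = p$worse_symbol,
           p_correct_better = p$p_correct_better)),
    trials_per_pair_per_block = config$trials_per_pair_per_block,
    block_size = config$block_size,
    criteria = as.list(config$criteria),
    max_blocks = config$max_blocks,
    metadata = config$metadata
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_task_json
#' @export
read_task_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  pst_task(
    pairs = lapply(obj$pairs, function(p)
      pst_pair(p$label, p$better_symbol, p$worse_symbol, p$p_correct_better)),
    trials_per_pair_per_block = obj$trials_per_pair_per_block,
    criteria = unlist(obj$criteria),
    max_blocks = obj$max_blocks,
    metadata = if (is.null(obj$metadata)) list() else obj$metadata
  )
}

#' Read and write agent parameters as JSON
#'
#' The JSON carries a `variant` field (`"single"` or `"dual"`) alongside the
#' parameter values.
#'
#' @param params An `"agent_params"`.
#' @param path File path.
#' @return `read_params_json()` returns an `"agent_params"`.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "agent_params"))
  obj <- c(list(variant = attr(params, "rate_structure")), unclass(params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$variant, "single"))
    agent_params(eta = obj$eta, v_scaling = obj$v_scaling, a = obj$a,
                 t0 = obj$t0)
  else
    agent_params(eta_pos = obj$eta_pos, eta_neg = obj$eta_neg,
                 v_scaling = obj$v_scaling, a = obj$a, t0 = obj$t0)
}
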