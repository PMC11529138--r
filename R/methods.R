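# S3 methods for rlddm_fit

.group_param_of <- function(colname) {
  sub("\\[.*$", "", sub("^(mu_|sigma_)", "", colname))
}

.back_transform_col <- function(colname, x) {
  if (!startsWith(colname, "mu_")) return(x)   # spreads stay on sampling scale
  if (grepl("^eta", .group_param_of(colname))) stats::plogis(x) else exp(x)
}

#' @export
print.rlddm_fit <- function(x, ...) {
  cat(sprintf("Hierarchical RL-DDM fit (%s learning rate%s)\n",
              x$rate_structure,
              if (x$prior_only) ", prior only" else ""))
  cat(sprintf("  %d subjects, %d conditions (%s); condition-varying: %s\n",
              length(x$subjects), length(x$conditions),
              paste(x$conditions, collapse = ", "),
              paste(x$condition_varying, collapse = ", ")))
  cat(sprintf("  %d chain(s) x %d draws (%d burn); max split-Rhat %.3f\n",
              x$sampler$chains, x$sampler$draws, x$sampler$burn,
              max(x$diagnostics$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Posterior summary of group-level parameters
#'
#' Group means are reported on the natural scale (learning rates as
#' probabilities, `v_scaling`, `a`, `t0` in their own units); group spreads
#' (`sigma_*`) stay on the sampling (logit/log) scale.
#'
#' @param object An `"rlddm_fit"`.
#' @param probs Quantiles to report.
#' @param ... Unused.
#' @return A data frame with one row per group-level parameter.
#' @export
summary.rlddm_fit <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  g <- .stack_group(object)
  rows <- lapply(colnames(g), function(cn) {
    x <- .back_transform_col(cn, g[, cn])
    qs <- stats::quantile(x, probs)
    data.frame(parameter = cn, mean = mean(x), sd = stats::sd(x),
               t(qs), rhat = object$diagnostics$rhat[[cn]],
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary.rlddm_fit", "data.frame")
  out
}

#' @export
print.summary.rlddm_fit <- function(x, ...) {
  cat("Group-level posterior summary (means on natural scale):\n")
  y <- x; class(y) <- "data.frame"
  y[-1] <- lapply(y[-1], round, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Posterior-mean group parameters
#'
#' @param object An `"rlddm_fit"`.
#' @param ... Unused.
#' @return Matrix of natural-scale posterior-mean group means, conditions in
#'   rows and parameters in columns (shared parameters repeated).
#' @export
coef.rlddm_fit <- function(object, ...) {
  g <- .stack_group(object)
  out <- matrix(NA_real_, length(object$conditions),
                length(object$par_names),
                dimnames = list(object$conditions, object$par_names))
  for (k in object$par_names) {
    if (k %in% object$condition_varying) {
      for (cc in object$conditions) {
        cn <- paste0("mu_", k, "[", cc, "]")
        out[cc, k] <- mean(.back_transform_col(cn, g[, cn]))
      }
    } else {
      cn <- paste0("mu_", k)
      out[, k] <- mean(.back_transform_col(cn, g[, cn]))
    }
  }
  out
}

#' Posterior density plots of group means
#'
#' One panel per parameter, one curve per condition (natural scale).
#'
#' @param x An `"rlddm_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rlddm_fit <- function(x, ...) {
  g <- .stack_group(x)
  pn <- x$par_names
  old <- graphics::par(mfrow = c(ceiling(length(pn) / 2), 2),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  cols <- seq_along(x$conditions) + 1
  for (k in pn) {
    if (k %in% x$condition_varying) {
      dens <- lapply(x$conditions, function(cc) {
        cn <- paste0("mu_", k, "[", cc, "]")
        stats::density(.back_transform_col(cn, g[, cn]))
      })
      xlim <- range(unlist(lapply(dens, `[[`, "x")))
      ylim <- c(0, max(unlist(lapply(dens, `[[`, "y"))))
      graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = k,
                     ylab = "density", main = k, ...)
      for (j in seq_along(dens)) graphics::lines(dens[[j]], col = cols[j])
      graphics::legend("topright", legend = x$conditions, col = cols,
                       lty = 1, bty = "n", cex = 0.8)
    } else {
      cn <- paste0("mu_", k)
      graphics::plot(stats::density(.back_transform_col(cn, g[, cn])),
                     xlab = k, main = k, ...)
    }
  }
  invisible(x)
}

#' Posterior-predictive simulation from a fit
#'
#' Re-runs full task sessions using each subject's posterior-mean parameters
#' with the learning diffusion agent.
#'
#' @param object An `"rlddm_fit"`.
#' @param nsim Number of replicate studies.
#' @param seed Optional seed.
#' @param task The task to simulate (default the standard one).
#' @param dt Diffusion integration step (seconds).
#' @param ... Unused.
#' @return A list of `nsim` trial data frames.
#' @export
simulate.rlddm_fit <- function(object, nsim = 1, seed = NULL,
                               task = make_standard_task(), dt = 1e-3, ...) {
  if (!is.null(seed)) set.seed(seed)
  theta_bar <- colMeans(do.call(rbind,
                                lapply(object$chains, `[[`, "subject")))
  ns <- length(object$subjects)
  theta_mat <- matrix(theta_bar, ns, length(object$par_names))
  lapply(seq_len(nsim), function(r) {
    sims <- lapply(seq_len(ns), function(i) {
      nat <- .natural(theta_mat[i, ], object$par_names)
      names(nat) <- object$par_names
      params <- if (object$rate_structure == "single")
        agent_params(eta = nat[["eta"]], v_scaling = nat[["v_scaling"]],
                     a = nat[["a"]], t0 = nat[["t0"]])
      else
        agent_params(eta_pos = nat[["eta_pos"]], eta_neg = nat[["eta_neg"]],
                     v_scaling = nat[["v_scaling"]], a = nat[["a"]],
                     t0 = nat[["t0"]])
      run_session(agent_rlddm(params, task, dt = dt), task,
                  subject_id = object$subjects[i],
                  condition = object$conditions[object$cond_index[i]])$trials
    })
    do.call(rbind, sims)
  })
}
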