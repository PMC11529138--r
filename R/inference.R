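# Hierarchical Bayesian estimation of RL-DDM parameters.
#
# Sampling scheme: adaptive Metropolis-within-Gibbs. Subject-level parameter
# vectors (on logit/log scales) get joint random-walk Metropolis updates
# against the wfpt trial likelihood plus their group prior; group means are
# conjugate-normal Gibbs updates; group spreads get random-walk updates on
# the log scale under half-normal priors. Proposal scales adapt during
# burn-in only.

#' Prior settings for the hierarchical RL-DDM
#'
#' Group means are normal on the sampling scale (logit for learning rates,
#' log for `v_scaling`, `a`, `t0`); group spreads are half-normal. Defaults
#' are weakly informative around typical values for two-alternative
#' probabilistic learning (learning rates near 0.2, drift scaling near 2,
#' boundary near 1.6, non-decision time near 0.35 s).
#'
#' @param ... Named overrides, each a list with any of `mean`, `sd`
#'   (group-mean prior) and `spread_scale` (half-normal scale of the group
#'   SD), e.g. `a = list(mean = log(2), sd = 1)`.
#' @return A list of per-parameter prior settings, class `"rlddm_priors"`.
#' @export
rlddm_priors <- function(...) {
  defaults <- list(
    eta       = list(mean = stats::qlogis(0.2), sd = 1.5, spread_scale = 1.0),
    eta_pos   = list(mean = stats::qlogis(0.2), sd = 1.5, spread_scale = 1.0),
    eta_neg   = list(mean = stats::qlogis(0.2), sd = 1.5, spread_scale = 1.0),
    v_scaling = list(mean = log(2),    sd = 1.0, spread_scale = 0.5),
    a         = list(mean = log(1.6),  sd = 0.8, spread_scale = 0.5),
    t0        = list(mean = log(0.35), sd = 0.8, spread_scale = 0.5)
  )
  over <- list(...)
  for (k in names(over)) {
    if (!k %in% names(defaults)) stop("unknown parameter: ", k)
    defaults[[k]][names(over[[k]])] <- over[[k]]
  }
  structure(defaults, class = "rlddm_priors")
}

.par_names <- function(rate_structure) {
  if (rate_structure == "single") c("eta", "v_scaling", "a", "t0")
  else c("eta_pos", "eta_neg", "v_scaling", "a", "t0")
}

# per-subject data in 0-based integer form for the C++ likelihood
.prep_data <- function(data) {
  need <- c("subject", "condition", "pair", "left", "right", "chosen",
            "chose_optimal", "feedback", "rt")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("trial table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(data) == 0L) stop("empty trial table")
  if (any(!is.finite(data$rt)) || any(data$rt <= 0))
    stop("non-positive or non-finite RTs in trial table; filter first")
  subjects <- unique(data$subject)
  if (length(subjects) < 2L) stop("at least 2 subjects are required")
  # infer each pair's better symbol from the chose_optimal coding
  other <- ifelse(data$chosen == data$left, data$right, data$left)
  better <- ifelse(data$chose_optimal, data$chosen, other)
  worse <- ifelse(data$chose_optimal, other, data$chosen)
  chk <- tapply(better, data$pair, function(x) length(unique(x)))
  if (any(chk != 1L))
    stop("inconsistent chose_optimal coding within a pair")
  symbols <- sort(unique(c(data$left, data$right)))
  idx <- function(s) match(s, symbols) - 1L
  cond_of <- tapply(data$condition, data$subject, function(x) unique(x))
  if (any(lengths(cond_of) != 1L))
    stop("subjects must belong to exactly one condition")
  conditions <- sort(unique(data$condition))
  subj_data <- lapply(subjects, function(s) {
    d <- data[data$subject == s, , drop = FALSE]
    d <- d[order(d$trial), , drop = FALSE]
    list(chosen = idx(d$chosen), better = idx(better[data$subject == s]),
         worse = idx(worse[data$subject == s]),
         chose_opt = d$chose_optimal, feedback = as.numeric(d$feedback),
         rt = d$rt, n = nrow(d))
  })
  names(subj_data) <- subjects
  rng <- range(data$rt)
  unif_dens <- if (diff(rng) > 0) 0.5 / diff(rng) else 1
  list(subjects = subjects, conditions = conditions,
       cond_index = match(unlist(cond_of[subjects]), conditions),
       subj_data = subj_data, n_symbols = length(symbols),
       unif_dens = unif_dens,
       fingerprint = c(n = nrow(data), ns = length(subjects),
                       sum_rt = sum(data$rt), sum_fb = sum(data$feedback)))
}

.natural <- function(theta, par_names) {
  out <- theta
  for (j in seq_along(par_names)) {
    out[j] <- if (grepl("^eta", par_names[j])) stats::plogis(theta[j])
              else exp(theta[j])
  }
  out
}

#' Fit the hierarchical RL-DDM
#'
#' Subject-level parameters (learning rate(s), drift scaling, boundary,
#' non-decision time) are drawn from condition-specific group distributions
#' (normal on logit/log scales); the trial likelihood is the response-coded
#' Wiener first-passage density of each (choice, RT), with the drift rate
#' recomputed trial-by-trial from the delta-rule Q-values implied by the
#' observed choice/feedback sequence, mixed with a uniform outlier
#' contaminant (`outlier_mix_prob`, default 5%) over the observed RT range.
#' The upper boundary is the pair's optimal symbol.
#'
#' @param data Trial data frame (see [read_trials()]); RTs in seconds,
#'   already outlier-filtered.
#' @param rate_structure `"dual"` (separate learning rates for positive and
#'   negative prediction errors) or `"single"`.
#' @param condition_varying Parameter names whose group means differ by
#'   condition; default: the learning rate(s), `v_scaling` and `a` (`t0`
#'   shared).
#' @param draws Total MCMC samples per chain, including burn-in (default
#'   10,000, of which 1,000 burn).
#' @param burn Discarded initial samples per chain.
#' @param chains Number of chains (>= 2 recommended for convergence checks).
#' @param seed Optional integer seed.
#' @param outlier_mix_prob Contaminant probability in `[0, 1)`.
#' @param priors A [rlddm_priors()] object.
#' @param prior_only If `TRUE`, drop the likelihood term (prior-predictive
#'   sanity checks).
#' @param progress Print a progress line per chain.
#' @return An object of class `"rlddm_fit"`; see [summary.rlddm_fit()],
#'   [compute_dic()], [directional_posterior_prob()].
#' @export
fit_rlddm <- function(data, rate_structure = c("dual", "single"),
                      condition_varying = NULL,
                      draws = 10000L, burn = 1000L, chains = 2L,
                      seed = NULL, outlier_mix_prob = 0.05,
                      priors = rlddm_priors(), prior_only = FALSE,
                      progress = FALSE) {
  rate_structure <- match.arg(rate_structure)
  stopifnot(draws > burn, burn >= 0L, chains >= 1L,
            outlier_mix_prob >= 0, outlier_mix_prob < 1)
  pn <- .par_names(rate_structure)
  if (is.null(condition_varying))
    condition_varying <- intersect(c("eta", "eta_pos", "eta_neg",
                                     "v_scaling", "a"), pn)
  if (!all(condition_varying %in% pn))
    stop("condition_varying contains unknown parameter(s): ",
         paste(setdiff(condition_varying, pn), collapse = ", "))
  prep <- .prep_data(data)
  ns <- length(prep$subjects); np <- length(pn)
  ng <- length(prep$conditions)
  is_rate <- grepl("^eta", pn)
  p_out <- outlier_mix_prob

  loglik_i <- function(i, theta_i) {
    if (prior_only) return(0)
    nat <- .natural(theta_i, pn)
    names(nat) <- pn
    ep <- if (rate_structure == "single") nat[["eta"]] else nat[["eta_pos"]]
    en <- if (rate_structure == "single") nat[["eta"]] else nat[["eta_neg"]]
    d <- prep$subj_data[[i]]
    .subject_loglik_cpp(d$chosen, d$better, d$worse, d$chose_opt, d$feedback,
                        d$rt, prep$n_symbols, ep, en, nat[["v_scaling"]],
                        nat[["a"]], nat[["t0"]], p_out, prep$unif_dens)
  }

  kept <- draws - burn
  mu_names <- unlist(lapply(pn, function(k) {
    if (k %in% condition_varying) paste0("mu_", k, "[", prep$conditions, "]")
    else paste0("mu_", k)
  }))
  sigma_names <- paste0("sigma_", pn)

  run_chain <- function(chain) {
    if (!is.null(seed)) set.seed((seed + 1009L * (chain - 1L)) %% 2147483629)
    prior_m <- vapply(pn, function(k) priors[[k]]$mean, numeric(1))
    prior_s <- vapply(pn, function(k) priors[[k]]$sd, numeric(1))
    prior_h <- vapply(pn, function(k) priors[[k]]$spread_scale, numeric(1))
    # overdispersed inits
    mu <- matrix(rep(prior_m, each = ng), ng, np) +
      matrix(stats::rnorm(ng * np, 0, 0.25), ng, np)
    for (k in which(!pn %in% condition_varying)) mu[, k] <- mu[1, k]
    sigma <- pmax(0.05, abs(stats::rnorm(np, prior_h / 3, 0.05)))
    theta <- mu[prep$cond_index, , drop = FALSE] +
      matrix(stats::rnorm(ns * np, 0, 0.1), ns, np)
    # keep initial t0 safely below each subject's fastest RT
    k_t0 <- match("t0", pn)
    for (i in seq_len(ns)) {
      cap <- log(0.6 * min(prep$subj_data[[i]]$rt))
      theta[i, k_t0] <- min(theta[i, k_t0], cap)
    }
    cur_ll <- vapply(seq_len(ns), function(i) loglik_i(i, theta[i, ]),
                     numeric(1))
    if (any(!is.finite(cur_ll)))
      stop("non-finite initial likelihood; check the trial table")
    # adaptive-Metropolis state per subject: proposal covariance learned
    # from the subject's own draw history during burn-in (Haario scheme),
    # scalar scale tuned to ~30% acceptance; both frozen after burn-in
    scale_i <- rep(0.4, ns)
    prop_L <- lapply(seq_len(ns), function(i) diag(0.08, np))
    run_mean <- theta; run_cov <- lapply(seq_len(ns), function(i)
      diag(0.08^2, np))
    n_hist <- rep(1, ns)
    acc <- rep(0L, ns); win <- 0L
    sig_scale <- rep(0.2, np); sig_acc <- rep(0L, np)
    # blocked translation moves: shift a condition's group mean together
    # with all of its subjects (moves the hierarchy along posterior ridges,
    # e.g. the learning-rate x drift-scaling trade-off)
    kv <- which(pn %in% condition_varying)
    nv <- length(kv)
    trans_L <- lapply(seq_len(ng), function(g) diag(0.05, nv))
    trans_scale <- rep(1, ng); trans_acc <- rep(0L, ng)
    trans_mean <- mu[, kv, drop = FALSE]
    trans_cov <- lapply(seq_len(ng), function(g) diag(0.05^2, nv))
    trans_n <- rep(1, ng)

    g_draws <- matrix(NA_real_, kept, length(mu_names) + length(sigma_names),
                      dimnames = list(NULL, c(mu_names, sigma_names)))
    s_draws <- matrix(NA_real_, kept, ns * np,
                      dimnames = list(NULL, paste0(rep(pn, each = ns), "[",
                                                   rep(prep$subjects, np), "]")))
    dev <- numeric(kept)

    for (it in seq_len(draws)) {
      # subject-level joint adaptive-Metropolis updates
      for (i in seq_len(ns)) {
        prop <- theta[i, ] +
          scale_i[i] * drop(prop_L[[i]] %*% stats::rnorm(np))
        lp_cur <- cur_ll[i] +
          sum(stats::dnorm(theta[i, ], mu[prep$cond_index[i], ], sigma,
                           log = TRUE))
        ll_prop <- loglik_i(i, prop)
        lp_prop <- ll_prop +
          sum(stats::dnorm(prop, mu[prep$cond_index[i], ], sigma, log = TRUE))
        if (is.finite(lp_prop) &&
            log(stats::runif(1)) < lp_prop - lp_cur) {
          theta[i, ] <- prop; cur_ll[i] <- ll_prop; acc[i] <- acc[i] + 1L
        }
        if (it <= burn) {             # Welford update of mean/covariance
          n_hist[i] <- n_hist[i] + 1
          dlt <- theta[i, ] - run_mean[i, ]
          run_mean[i, ] <- run_mean[i, ] + dlt / n_hist[i]
          run_cov[[i]] <- run_cov[[i]] * (n_hist[i] - 2) / (n_hist[i] - 1) +
            tcrossprod(dlt) / n_hist[i]
        }
      }
      win <- win + 1L
      # blocked translation per condition over condition-varying parameters
      if (nv > 0) for (g in seq_len(ng)) {
        members <- which(prep$cond_index == g)
        delta <- numeric(np)
        delta[kv] <- trans_scale[g] * drop(trans_L[[g]] %*% stats::rnorm(nv))
        ll_new <- vapply(members, function(i) loglik_i(i, theta[i, ] + delta),
                         numeric(1))
        mu_new <- mu[g, ] + delta
        lr <- sum(ll_new) - sum(cur_ll[members]) +
          sum(stats::dnorm(mu_new[kv], prior_m[kv], prior_s[kv], log = TRUE)) -
          sum(stats::dnorm(mu[g, kv], prior_m[kv], prior_s[kv], log = TRUE))
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          theta[members, ] <- sweep(theta[members, , drop = FALSE], 2, delta,
                                    "+")
          mu[g, kv] <- mu_new[kv]
          cur_ll[members] <- ll_new
          trans_acc[g] <- trans_acc[g] + 1L
        }
        if (it <= burn) {
          trans_n[g] <- trans_n[g] + 1
          dlt <- mu[g, kv] - trans_mean[g, ]
          trans_mean[g, ] <- trans_mean[g, ] + dlt / trans_n[g]
          trans_cov[[g]] <- trans_cov[[g]] * (trans_n[g] - 2) / (trans_n[g] - 1) +
            tcrossprod(dlt) / trans_n[g]
        }
      }
      # group means: conjugate Gibbs
      for (k in seq_len(np)) {
        if (pn[k] %in% condition_varying) {
          for (g in seq_len(ng)) {
            th <- theta[prep$cond_index == g, k]
            prec <- length(th) / sigma[k]^2 + 1 / prior_s[k]^2
            m <- (sum(th) / sigma[k]^2 + prior_m[k] / prior_s[k]^2) / prec
            mu[g, k] <- stats::rnorm(1, m, sqrt(1 / prec))
          }
        } else {
          th <- theta[, k]
          prec <- ns / sigma[k]^2 + 1 / prior_s[k]^2
          m <- (sum(th) / sigma[k]^2 + prior_m[k] / prior_s[k]^2) / prec
          mu[, k] <- stats::rnorm(1, m, sqrt(1 / prec))
        }
      }
      # group-spread scale moves: rescale sigma_k and the subject deviations
      # around their group means jointly (theta prior terms and the theta
      # Jacobian cancel, leaving likelihood + sigma prior + log c)
      if (it %% 2L == 0L) for (k in seq_len(np)) {
        lc <- 0.3 * stats::rnorm(1); cc <- exp(lc)
        s_new <- sigma[k] * cc
        th_new <- theta
        th_new[, k] <- mu[prep$cond_index, k] +
          cc * (theta[, k] - mu[prep$cond_index, k])
        ll_new <- vapply(seq_len(ns), function(i) loglik_i(i, th_new[i, ]),
                         numeric(1))
        lr <- sum(ll_new) - sum(cur_ll) +
          (sigma[k]^2 - s_new^2) / (2 * prior_h[k]^2) + lc
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          theta <- th_new; sigma[k] <- s_new; cur_ll <- ll_new
        }
      }
      # group spreads: RW-MH on log scale, half-normal prior
      for (k in seq_len(np)) {
        ls <- log(sigma[k]); ls_p <- ls + sig_scale[k] * stats::rnorm(1)
        s_p <- exp(ls_p)
        th <- theta[, k]; m_k <- mu[prep$cond_index, k]
        lt_cur <- sum(stats::dnorm(th, m_k, sigma[k], log = TRUE)) -
          sigma[k]^2 / (2 * prior_h[k]^2) + ls
        lt_prop <- sum(stats::dnorm(th, m_k, s_p, log = TRUE)) -
          s_p^2 / (2 * prior_h[k]^2) + ls_p
        if (log(stats::runif(1)) < lt_prop - lt_cur) {
          sigma[k] <- s_p; sig_acc[k] <- sig_acc[k] + 1L
        }
      }
      # adapt during burn-in only
      if (it <= burn && win == 25L) {
        rate <- acc / win
        scale_i <- pmin(10, pmax(1e-3, scale_i * exp(0.8 * (rate - 0.3))))
        if (it >= 200L) {
          for (i in seq_len(ns)) {
            ch <- tryCatch(chol(run_cov[[i]] + diag(2.5e-5, np)),
                           error = function(e) NULL)
            if (!is.null(ch)) prop_L[[i]] <- t(ch) * (2.38 / sqrt(np))
          }
          if (nv > 0) for (g in seq_len(ng)) {
            ch <- tryCatch(chol(trans_cov[[g]] + diag(2.5e-5, nv)),
                           error = function(e) NULL)
            if (!is.null(ch)) trans_L[[g]] <- t(ch) * (2.38 / sqrt(nv))
          }
        }
        if (nv > 0) {
          trans_scale <- pmin(10, pmax(1e-3, trans_scale *
                                         exp(0.8 * (trans_acc / win - 0.25))))
          trans_acc[] <- 0L
        }
        sig_rate <- sig_acc / win
        sig_scale <- pmin(5, pmax(1e-3, sig_scale * exp(0.7 * (sig_rate - 0.4))))
        acc[] <- 0L; sig_acc[] <- 0L; win <- 0L
      } else if (win == 50L) {
        acc[] <- 0L; sig_acc[] <- 0L; win <- 0L
      }
      if (it > burn) {
        j <- it - burn
        row <- numeric(0)
        for (k in seq_len(np)) {
          row <- c(row, if (pn[k] %in% condition_varying) mu[, k]
                   else mu[1, k])
        }
        g_draws[j, ] <- c(row, sigma)
        s_draws[j, ] <- as.vector(theta)
        dev[j] <- -2 * sum(cur_ll)
      }
    }
    if (progress)
      message(sprintf("chain %d done (mean subject acceptance %.2f)",
                      chain, mean(acc / max(win, 1))))
    list(group = g_draws, subject = s_draws, deviance = dev)
  }

  chains_out <- lapply(seq_len(chains), run_chain)
  rhat <- .split_rhat(lapply(chains_out, `[[`, "group"))
  if (any(rhat > 1.05, na.rm = TRUE))
    warning("convergence diagnostics above threshold (split-Rhat > 1.05): ",
            paste(names(rhat)[rhat > 1.05], collapse = ", "))

  structure(list(
    chains = chains_out,
    par_names = pn, conditions = prep$conditions,
    subjects = prep$subjects, cond_index = prep$cond_index,
    rate_structure = rate_structure, condition_varying = condition_varying,
    outlier_mix_prob = p_out, prior_only = prior_only,
    priors = priors,
    sampler = list(draws = draws, burn = burn, chains = chains, seed = seed),
    diagnostics = list(rhat = rhat),
    prep = prep
  ), class = "rlddm_fit")
}

# split-Rhat over a list of per-chain draw matrices (same columns)
.split_rhat <- function(chain_mats) {
  halves <- list()
  for (m in chain_mats) {
    n <- nrow(m); h <- floor(n / 2)
    halves <- c(halves, list(m[seq_len(h), , drop = FALSE],
                             m[(n - h + 1):n, , drop = FALSE]))
  }
  vapply(colnames(chain_mats[[1]]), function(cn) {
    draws <- lapply(halves, function(m) m[, cn])
    n <- length(draws[[1]]); m <- length(draws)
    means <- vapply(draws, mean, numeric(1))
    vars <- vapply(draws, stats::var, numeric(1))
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W <= 0) return(NA_real_)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

# stacked group-level draws across chains
.stack_group <- function(fit) {
  do.call(rbind, lapply(fit$chains, `[[`, "group"))
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(theta_bar)`: the mean posterior
#' deviance plus the effective number of parameters, where `D(theta_bar)` is
#' the deviance at the posterior mean of the subject-level parameters
#' (classic plug-in form). Lower is better.
#'
#' @param fit An `"rlddm_fit"`.
#' @return The DIC value, with attributes `pD`, `mean_deviance` and
#'   `deviance_at_mean`.
#' @seealso [dic_value()] for the bare arithmetic, [compare_models()].
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "rlddm_fit"))
  if (fit$prior_only) stop("DIC undefined for a prior-only fit")
  dev <- unlist(lapply(fit$chains, `[[`, "deviance"))
  theta_bar <- colMeans(do.call(rbind, lapply(fit$chains, `[[`, "subject")))
  ns <- length(fit$subjects); pn <- fit$par_names
  theta_mat <- matrix(theta_bar, ns, length(pn))
  ll <- 0
  for (i in seq_len(ns)) {
    nat <- .natural(theta_mat[i, ], pn); names(nat) <- pn
    ep <- if (fit$rate_structure == "single") nat[["eta"]] else nat[["eta_pos"]]
    en <- if (fit$rate_structure == "single") nat[["eta"]] else nat[["eta_neg"]]
    d <- fit$prep$subj_data[[i]]
    ll <- ll + .subject_loglik_cpp(d$chosen, d$better, d$worse, d$chose_opt,
                                   d$feedback, d$rt, fit$prep$n_symbols,
                                   ep, en, nat[["v_scaling"]], nat[["a"]],
                                   nat[["t0"]], fit$outlier_mix_prob,
                                   fit$prep$unif_dens)
  }
  dic_value(dev, -2 * ll)
}

#' DIC from a deviance trace and a plug-in deviance
#'
#' @param deviance_trace Retained posterior deviance values.
#' @param deviance_at_mean Deviance at the posterior-mean parameters.
#' @return The DIC value with attributes `pD`, `mean_deviance`,
#'   `deviance_at_mean`.
#' @export
dic_value <- function(deviance_trace, deviance_at_mean) {
  if (length(deviance_trace) < 2L)
    stop("at least 2 retained draws are required")
  dbar <- mean(deviance_trace)
  pd <- dbar - deviance_at_mean
  structure(dbar + pd, pD = pd, mean_deviance = dbar,
            deviance_at_mean = deviance_at_mean)
}

#' Compare fitted models by DIC
#'
#' @param fits Named list of `"rlddm_fit"` objects fitted to the same data.
#' @return An object of class `"rlddm_comparison"`: `dic_by_model`,
#'   `preferred` (lowest DIC; ties resolved by name order and flagged),
#'   `delta_dic` (DIC minus the minimum), `tie`.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2L, !is.null(names(fits)))
  fps <- lapply(fits, function(f) f$prep$fingerprint)
  if (!all(vapply(fps[-1], function(fp) isTRUE(all.equal(fp, fps[[1]])),
                  logical(1))))
    stop("models were fitted on different datasets")
  dics <- vapply(fits, function(f) as.numeric(compute_dic(f)), numeric(1))
  compare_dic(dics)
}

#' @rdname compare_models
#' @param dics Named numeric vector of DIC values.
#' @export
compare_dic <- function(dics) {
  stopifnot(is.numeric(dics), length(dics) >= 2L, !is.null(names(dics)))
  minimum <- min(dics)
  tied <- names(dics)[dics == minimum]
  preferred <- sort(tied)[1]
  structure(list(dic_by_model = dics, preferred = preferred,
                 delta_dic = dics - minimum, tie = length(tied) > 1L),
            class = "rlddm_comparison")
}

#' @export
print.rlddm_comparison <- function(x, ...) {
  cat("DIC model comparison:\n")
  for (m in names(x$dic_by_model))
    cat(sprintf("  %s: DIC %.1f (delta %.1f)%s\n", m, x$dic_by_model[[m]],
                x$delta_dic[[m]], if (m == x$preferred) "  <- preferred" else ""))
  if (x$tie) cat("  (tie: preferred by name order)\n")
  invisible(x)
}

#' Directional posterior probability of a condition contrast
#'
#' The proportion of retained draws in which the group-level mean of
#' `parameter` (on the natural scale) satisfies the stated direction between
#' two conditions — e.g. p(mindfulness > control) for `eta_pos`.
#'
#' @param fit An `"rlddm_fit"`.
#' @param parameter One of the fit's condition-varying parameters.
#' @param contrast Character vector `c(A, B)` of condition labels.
#' @param direction `">"` (A greater than B) or `"<"`.
#' @return A probability in `[0, 1]`.
#' @export
directional_posterior_prob <- function(fit, parameter,
                                       contrast = fit$conditions[c(2, 1)],
                                       direction = c(">", "<")) {
  stopifnot(inherits(fit, "rlddm_fit"), length(contrast) == 2L)
  direction <- match.arg(direction)
  if (!parameter %in% fit$condition_varying)
    stop("parameter '", parameter, "' does not vary by condition in this fit")
  if (!all(contrast %in% fit$conditions))
    stop("unknown condition(s): ",
         paste(setdiff(contrast, fit$conditions), collapse = ", "))
  g <- .stack_group(fit)
  back <- if (grepl("^eta", parameter)) stats::plogis else exp
  va <- back(g[, paste0("mu_", parameter, "[", contrast[1], "]")])
  vb <- back(g[, paste0("mu_", parameter, "[", contrast[2], "]")])
  directional_prob(va - vb, direction)
}

#' @rdname directional_posterior_prob
#' @param diffs Numeric vector of posterior difference draws (A minus B).
#' @export
directional_prob <- function(diffs, direction = c(">", "<")) {
  direction <- match.arg(direction)
  if (direction == ">") mean(diffs > 0) else mean(diffs < 0)
}

#' Posterior-odds Bayes factor from a directional probability
#'
#' `BF = (1 - p) / p`: the posterior odds of the favoured direction against
#' the reported tail. Under this convention a directional probability of
#' 0.061 implies a Bayes factor of about 15, 0.013 about 76 and 0.377 about
#' 2 (nearest integers).
#'
#' @param p Directional posterior probability, strictly inside (0, 1).
#' @return The Bayes factor.
#' @export
bayes_factor_from_p <- function(p) {
  if (any(p <= 0 | p >= 1))
    stop("p must lie strictly inside (0, 1); degenerate odds")
  (1 - p) / p
}
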