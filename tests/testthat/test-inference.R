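test_that("DIC arithmetic follows the plug-in definition", {
  d <- dic_value(c(10, 12, 14), 9)
  expect_equal(as.numeric(d), 15)
  expect_equal(attr(d, "pD"), 3)
  expect_equal(attr(d, "mean_deviance"), 12)
  const <- dic_value(rep(7, 10), 7)
  expect_equal(as.numeric(const), 7)
  expect_equal(attr(const, "pD"), 0)
  expect_error(dic_value(10, 9), "2 retained draws")
})

test_that("model comparison picks the DIC minimum with stable ties", {
  cmp <- compare_dic(c(m1 = 100, m2 = 90))
  expect_equal(cmp$preferred, "m2")
  expect_equal(unname(cmp$delta_dic), c(10, 0))
  expect_false(cmp$tie)
  tie <- compare_dic(c(b = 50, a = 50))
  expect_true(tie$tie)
  expect_equal(tie$preferred, "a")
})

test_that("directional probabilities count draws in the stated tail", {
  expect_equal(directional_prob(c(1, 2, 3), ">"), 1.0)
  expect_equal(directional_prob(c(-1, 1, 2, 3), ">"), 0.75)
  expect_equal(directional_prob(c(-1, 1, 2, 3), "<"), 0.25)
  set.seed(15)
  sym <- rnorm(20000)
  expect_lt(abs(directional_prob(sym, ">") - 0.5), 0.02)
})

test_that("the posterior-odds Bayes factor reproduces its conventions", {
  expect_equal(bayes_factor_from_p(0.5), 1.0)
  expect_equal(round(bayes_factor_from_p(0.061)), 15)
  expect_equal(round(bayes_factor_from_p(0.013)), 76)
  expect_error(bayes_factor_from_p(0), "strictly inside")
  expect_error(bayes_factor_from_p(1), "strictly inside")
})

test_that("degenerate trial tables are rejected up front", {
  st <- small_study()
  expect_error(fit_rlddm(st$trials[0, ]), "empty")
  one <- st$trials[st$trials$subject == st$trials$subject[1], ]
  expect_error(fit_rlddm(one), "2 subjects")
  bad <- st$trials; bad$rt[3] <- -1
  expect_error(fit_rlddm(bad), "non-positive")
  expect_error(fit_rlddm(st$trials, condition_varying = c("zeta")),
               "unknown parameter")
})

test_that("with no data the posterior reproduces the prior", {
  st <- small_study()
  pr <- rlddm_priors()
  fit <- quick_fit(st$trials, rate_structure = "dual", prior_only = TRUE)
  g <- do.call(rbind, lapply(fit$chains, `[[`, "group"))
  for (k in c("eta_pos", "a")) {
    for (cc in c("control", "mindfulness")) {
      draws <- g[, paste0("mu_", k, "[", cc, "]")]
      lo <- pr[[k]]$mean - 1.96 * pr[[k]]$sd
      hi <- pr[[k]]$mean + 1.96 * pr[[k]]$sd
      expect_gt(mean(draws > lo & draws < hi), 0.85)
    }
  }
  expect_error(compute_dic(fit), "prior-only")
})

test_that("posterior draws respect parameter supports", {
  st <- small_study()
  d <- filter_rt_outliers(st$trials)$trials
  fit <- quick_fit(d, rate_structure = "dual")
  g <- do.call(rbind, lapply(fit$chains, `[[`, "group"))
  nat_rates <- plogis(g[, grep("^mu_eta", colnames(g))])
  expect_true(all(nat_rates > 0 & nat_rates < 1))
  expect_true(all(exp(g[, "mu_a[control]"]) > 0))
  expect_true(all(g[, grep("^sigma_", colnames(g))] > 0))
  # subject-level draws too
  s <- do.call(rbind, lapply(fit$chains, `[[`, "subject"))
  rates <- plogis(s[, grep("^eta", colnames(s))])
  expect_true(all(rates > 0 & rates < 1))
})

test_that("a short fit recovers the dual-rate asymmetry direction", {
  set.seed(16)
  sds <- c(eta_pos = 0.3, eta_neg = 0.3, v_scaling = 0.2, a = 0.15,
           t0 = 0.1)
  means <- c(eta_pos = 0.3, eta_neg = 0.05, v_scaling = 2.5, a = 1.6,
             t0 = 0.35)
  cfg <- study_config(8, list(condition_params("g1", means, sds),
                              condition_params("g2", means, sds)),
                      seed = 3)
  st <- generate_study(cfg)
  d <- filter_rt_outliers(st$trials)$trials
  fit <- suppressWarnings(
    fit_rlddm(d, "dual", draws = 800, burn = 300, chains = 1, seed = 4))
  s <- do.call(rbind, lapply(fit$chains, `[[`, "group"))
  dp <- plogis(s[, "mu_eta_pos[g1]"]) + plogis(s[, "mu_eta_pos[g2]"])
  dn <- plogis(s[, "mu_eta_neg[g1]"]) + plogis(s[, "mu_eta_neg[g2]"])
  expect_gt(directional_prob(dp - dn, ">"), 0.95)
})

test_that("contrasts demand condition-varying parameters and known labels", {
  st <- small_study()
  d <- filter_rt_outliers(st$trials)$trials
  fit <- quick_fit(d, rate_structure = "dual")
  expect_error(directional_posterior_prob(fit, "t0"), "does not vary")
  expect_error(directional_posterior_prob(fit, "eta_pos", c("x", "control")),
               "unknown condition")
  p <- directional_posterior_prob(fit, "a", c("mindfulness", "control"), ">")
  expect_true(p >= 0 && p <= 1)
})

test_that("fit methods print, summarise, and simulate coherently", {
  st <- small_study()
  d <- filter_rt_outliers(st$trials)$trials
  fit <- quick_fit(d, rate_structure = "dual")
  expect_output(print(fit), "Hierarchical RL-DDM")
  s <- summary(fit)
  expect_true(all(c("parameter", "mean", "rhat") %in% names(s)))
  cf <- coef(fit)
  expect_equal(rownames(cf), c("control", "mindfulness"))
  expect_true(all(cf[, "eta_pos"] > 0 & cf[, "eta_pos"] < 1))
  expect_equal(cf["control", "t0"], cf["mindfulness", "t0"])  # shared
  sim <- simulate(fit, nsim = 1, seed = 1, dt = 2e-3)
  expect_equal(length(sim), 1L)
  expect_true(all(sim[[1]]$rt > 0))
  expect_setequal(unique(sim[[1]]$subject), fit$subjects)
})
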