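test_that("Q-values initialise uninformed and update by the delta rule", {
  q <- init_q(standard_task)
  expect_equal(unname(q), rep(0.5, 6))
  expect_identical(init_q(standard_task), init_q(standard_task))
  p1 <- agent_params(eta = 0.2, v_scaling = 2, a = 1.5, t0 = 0.3)
  expect_equal(trial_drift(q, standard_task$pairs$AB, p1), 0)

  q2 <- update_q(q, "A", 1, p1)
  expect_equal(q2[["A"]], 0.6)
  expect_equal(q2[names(q2) != "A"], q[names(q) != "A"])

  p0 <- agent_params(eta = 0, v_scaling = 2, a = 1.5, t0 = 0.3)
  q3 <- q; q3[["A"]] <- 0.7
  expect_equal(update_q(q3, "A", 0, p0)[["A"]], 0.7)

  pd <- agent_params(eta_pos = 0.3, eta_neg = 0.1, v_scaling = 2, a = 1.5,
                     t0 = 0.3)
  expect_equal(update_q(q, "A", 1, pd)[["A"]], 0.65)
  expect_equal(update_q(q, "A", 0, pd)[["A"]], 0.45)
  expect_error(update_q(q, "Z", 1, p1), "unknown symbol")
})

test_that("Q-values stay in [0,1] and contract towards the reward", {
  set.seed(51)
  for (r in 1:20) {
    params <- agent_params(eta_pos = runif(1), eta_neg = runif(1),
                           v_scaling = 1, a = 1, t0 = 0)
    q <- init_q(standard_task)
    for (t in 1:100) {
      sym <- sample(names(q), 1)
      rew <- rbinom(1, 1, 0.5)
      gap_before <- abs(q[[sym]] - rew)
      rate <- if (rew - q[[sym]] > 0) params$eta_pos else params$eta_neg
      q <- update_q(q, sym, rew, params)
      expect_true(all(q >= 0 & q <= 1))
      expect_lte(abs(q[[sym]] - rew), (1 - rate) * gap_before + 1e-12)
    }
  }
})

test_that("trial drift is the scaled Q-difference with antisymmetry", {
  params <- agent_params(eta = 0.1, v_scaling = 2, a = 1.5, t0 = 0.3)
  q <- init_q(standard_task)
  q[["A"]] <- 0.8; q[["B"]] <- 0.2
  expect_equal(trial_drift(q, standard_task$pairs$AB, params), 1.2)
  q_swapped <- q; q_swapped[["A"]] <- 0.2; q_swapped[["B"]] <- 0.8
  expect_equal(trial_drift(q_swapped, standard_task$pairs$AB, params),
               -trial_drift(q, standard_task$pairs$AB, params))
})

test_that("closed-form choice probability behaves and guards its domain", {
  expect_equal(choice_prob_upper(2, 0), 0.5)
  expect_equal(choice_prob_upper(2, 1), 1 / (1 + exp(-2)))
  expect_equal(choice_prob_upper(2, 50), 1)
  expect_error(choice_prob_upper(0, 1), "positive")
  expect_error(choice_prob_upper(-1, 1), "positive")
})

test_that("wfpt density is zero before t0 and conserves probability", {
  expect_identical(wfpt_logdensity(c(0.1, 0.3), 2, 1, 0.3, "upper"),
                   c(-Inf, -Inf))
  iu <- integrate(function(t) exp(wfpt_logdensity(t, 2, 1, 0.3, "upper")),
                  0.3, 40, rel.tol = 1e-10)$value
  il <- integrate(function(t) exp(wfpt_logdensity(t, 2, 1, 0.3, "lower")),
                  0.3, 40, rel.tol = 1e-10)$value
  expect_lt(abs(iu + il - 1), 1e-4)
  expect_lt(abs(iu - choice_prob_upper(2, 1)), 1e-6)
  # numerically stable across the contracted decision-time range
  t <- 0.3 + 10^seq(-4, log10(20), length.out = 50)
  ld <- wfpt_logdensity(t, 2, 1, 0.3, "upper")
  expect_true(all(is.finite(ld)))
  expect_error(wfpt_logdensity(0.5, NA, 1, 0.3), "finite")
})

test_that("first-passage simulation matches the analytic absorption law", {
  set.seed(61)
  fp0 <- simulate_first_passage(3e4, 1.5, 0, 0.25)
  expect_true(all(fp0$rt > 0.25))
  expect_lt(abs(mean(fp0$upper) - 0.5), 0.01)
  set.seed(62)
  fp1 <- simulate_first_passage(3e4, 2, 1, 0)
  expect_lt(abs(mean(fp1$upper) - choice_prob_upper(2, 1)), 0.01)
})

test_that("simulated agent trials respect the response coding", {
  params <- agent_params(eta = 0.1, v_scaling = 3, a = 2, t0 = 0.3)
  pair <- standard_task$pairs$AB
  set.seed(71)
  q0 <- init_q(standard_task)
  res <- replicate(5000, simulate_agent_trial(q0, pair, params, dt = 1e-3),
                   simplify = FALSE)
  opt <- vapply(res, function(r) identical(r$chosen, "A"), logical(1))
  up <- vapply(res, `[[`, logical(1), "upper")
  expect_identical(opt, up)                    # coding invariant
  expect_lt(abs(mean(opt) - 0.5), 0.02)        # zero drift at start

  q1 <- q0; q1[["A"]] <- 1; q1[["B"]] <- 0     # saturated learning, v = 3
  set.seed(72)
  res1 <- replicate(4000, simulate_agent_trial(q1, pair, params, dt = 1e-3),
                    simplify = FALSE)
  p_opt <- mean(vapply(res1, function(r) identical(r$chosen, "A"),
                       logical(1)))
  expect_lt(abs(p_opt - choice_prob_upper(2, 3)), 0.015)
})

test_that("learning diffusion agents learn; zero-rate agents do not", {
  set.seed(81)
  p_zero <- agent_params(eta = 0, v_scaling = 2.5, a = 1.6, t0 = 0.35)
  acc0 <- replicate(12, {
    s <- run_session(agent_rlddm(p_zero, no_stop_task, dt = 1e-3),
                     no_stop_task)
    mean(s$trials$chose_optimal)
  })
  expect_lt(abs(mean(acc0) - 0.5), 0.02)

  set.seed(82)
  p_fast <- agent_params(eta = 0.5, v_scaling = 6, a = 2, t0 = 0.35)
  s <- run_session(agent_rlddm(p_fast, standard_task, dt = 1e-3),
                   standard_task)
  ab <- s$trials[s$trials$pair == "AB", ]
  late <- ab[ab$pair_encounter > 10, ]
  expect_gt(mean(late$chose_optimal), 0.85)
})
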