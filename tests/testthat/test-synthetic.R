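test_that("study generation is deterministic under the master seed", {
  cfg <- study_preset("paper_like", n_subjects = 3, seed = 9, dt = 2e-3)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$truth, s2$truth)
})

test_that("every subject runs whole blocks up to the session cap", {
  st <- small_study()
  counts <- table(st$trials$subject)
  expect_true(all(counts %% 60 == 0))
  expect_true(all(counts >= 60 & counts <= 360))
  expect_equal(nrow(st$truth), 12L)
  # excluded subjects are flagged, never dropped
  expect_true(all(st$truth$subject %in% unique(st$trials$subject)))
})

test_that("stored ground truth reproduces the stored trials exactly", {
  st <- small_study()
  sid <- st$truth$subject[5]
  re <- resimulate_subject(st, sid)
  orig <- st$trials[st$trials$subject == sid, ]
  rownames(orig) <- NULL
  expect_identical(re, orig)
})

test_that("presets validate and differ only in the stated directions", {
  for (nm in c("null", "paper_like")) {
    cfg <- study_preset(nm, n_subjects = 5, seed = 2)
    expect_s3_class(cfg, "study_config")
    expect_equal(cfg$rate_structure, "dual")
    expect_setequal(names(cfg$conditions), c("control", "mindfulness"))
  }
  nullc <- study_preset("null")$conditions
  expect_identical(nullc$control$mu, nullc$mindfulness$mu)
  pl <- study_preset("paper_like")$conditions
  expect_gt(pl$mindfulness$mu[["eta_pos"]], pl$control$mu[["eta_pos"]])
  expect_lt(pl$mindfulness$mu[["v_scaling"]], pl$control$mu[["v_scaling"]])
  expect_gt(pl$mindfulness$mu[["a"]], pl$control$mu[["a"]])
  expect_equal(pl$mindfulness$mu[["eta_neg"]], pl$control$mu[["eta_neg"]])
  expect_equal(pl$mindfulness$mu[["t0"]], pl$control$mu[["t0"]])
  expect_error(study_preset("bogus"), "arg")
})

test_that("subject draws respect the configured group distributions", {
  cond <- study_preset("paper_like")$conditions$mindfulness
  set.seed(12)
  d <- draw_subject_params(cond, 200L)
  expect_true(all(d$eta_pos > 0 & d$eta_pos < 1))
  expect_true(all(d$a > 0) && all(d$t0 > 0))
  # back-transformed sample means within 3 standard errors of group means
  for (k in names(cond$mu)) {
    z <- if (k %in% c("eta_pos", "eta_neg")) stats::qlogis(d[[k]])
         else log(d[[k]])
    se <- cond$sigma[[k]] / sqrt(200)
    expect_lt(abs(mean(z) - cond$mu[[k]]), 3 * se + 1e-12)
  }
})

test_that("learning presets beat zero-learning agents on the first block", {
  st <- small_study()
  b1 <- st$trials[st$trials$block == 1 & st$trials$pair == "AB", ]
  set.seed(14)
  task <- make_standard_task()
  p0 <- agent_params(eta = 0, v_scaling = 2.5, a = 1.6, t0 = 0.35)
  b0 <- do.call(rbind, lapply(1:12, function(i) {
    s <- run_session(agent_rlddm(p0, task, dt = 2e-3), task,
                     subject_id = paste0("z", i))
    s$trials[s$trials$block == 1 & s$trials$pair == "AB", ]
  }))
  expect_gt(mean(b1$chose_optimal), mean(b0$chose_optimal))
})

test_that("studies round-trip through the on-disk format", {
  st <- small_study()
  dir <- withr::local_tempdir()
  write_study(st, dir)
  back <- read_trials(file.path(dir, "trials.csv"))
  expect_equal(nrow(back), nrow(st$trials))
  expect_equal(back$rt, st$trials$rt, tolerance = 1e-12)
  expect_identical(back$chosen, st$trials$chosen)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, st$config$seed)
  expect_match(man$note, "synthetic")
})
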