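test_that("simulation is deterministic given the seed, end to end", {
  task <- default_task()
  a <- run_acquisition(task, n_sessions = 2, n_trials = 200, seed = 7,
                       keep_trials = TRUE, record_events = TRUE)
  b <- run_acquisition(task, n_sessions = 2, n_trials = 200, seed = 7,
                       keep_trials = TRUE, record_events = TRUE)
  expect_identical(a$sessions, b$sessions)
  expect_identical(a$trials, b$trials)
  expect_identical(a$events, b$events)
  expect_identical(a$values$values, b$values$values)
  # different seed, different stream
  c_ <- run_acquisition(task, n_sessions = 2, n_trials = 200, seed = 8,
                        keep_trials = TRUE)
  expect_false(identical(a$trials, c_$trials))

  # identical CSV outputs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_run_outputs(a, d1); write_run_outputs(b, d2)
  for (f in c("sessions.csv", "trials.csv", "td_events.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_true(file.exists(file.path(d1, "run_manifest.json")))
  # deterministic event ordering: trial index non-decreasing within session
  for (s in unique(a$events$session)) {
    expect_true(all(diff(a$events$trial[a$events$session == s]) >= 0))
  }
})

test_that("any session of a run can be reproduced in isolation", {
  task <- default_task()
  eng <- engagement_params()
  run <- run_acquisition(task, eng, n_sessions = 3, n_trials = 150,
                         seed = 99, keep_trials = TRUE)
  # replay session 3 alone from the values after session 2
  first2 <- run_acquisition(task, eng, n_sessions = 2, n_trials = 150,
                            seed = 99)
  redo <- run_session(task, eng, n_trials = 150, V = first2$values,
                      seed = observeTD:::.session_seed(99, 3),
                      session_index = 3)
  expect_equal(redo$summary,
               run$sessions[3, setdiff(names(run$sessions), NULL)],
               ignore_attr = TRUE)
  expect_identical(redo$trials$reward,
                   run$trials$reward[run$trials$session == 3])
})

test_that("session bookkeeping holds for degenerate and standard sessions", {
  out <- run_session(default_task(), n_trials = 480, seed = 12)
  s <- out$summary
  expect_equal(s$bias, s$n_info / s$n_choice)
  expect_true(s$ci_low <= s$bias && s$bias <= s$ci_high)
  # a single forced trial leaves the bias undefined but not broken
  forced <- build_observing_task(trial_mixture = c(1, 0, 0))
  one <- run_session(forced, n_trials = 1, seed = 1)
  expect_true(one$summary$undefined_bias)
  expect_identical(one$summary$n_choice, 0L)
  expect_true(is.na(one$summary$bias))
  expect_identical(one$trials$chosen_option, "none")
})

test_that("Clopper-Pearson intervals match the exact binomial construction", {
  expect_identical(clopper_pearson(0, 10)[["low"]], 0)
  expect_identical(clopper_pearson(10, 10)[["high"]], 1)
  # frozen from the exact interval for 5/10 at 95%
  ci <- clopper_pearson(5, 10)
  expect_equal(unname(ci), c(0.187086, 0.812914), tolerance = 1e-4)
  # independent oracle: R's own exact binomial test
  for (kn in list(c(3, 17), c(40, 160), c(159, 160))) {
    bt <- stats::binom.test(kn[1], kn[2])$conf.int
    expect_equal(unname(clopper_pearson(kn[1], kn[2])), as.numeric(bt),
                 tolerance = 1e-12)
  }
  expect_error(clopper_pearson(5, 0), "n >= 1")
  expect_error(clopper_pearson(-1, 10), "0 <= k")
  expect_error(clopper_pearson(11, 10), "0 <= k")
})

test_that("the engine realizes the stated reward and trial-type marginals", {
  res <- engine_run(default_task(), 2e4, seed = 41)
  frac_large <- mean(res$reward == 1)
  expect_lt(abs(frac_large - 0.5), 3 * sqrt(0.25 / 2e4))
  frac_choice <- mean(res$type == 3L)
  expect_lt(abs(frac_choice - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / 2e4))
})

test_that("forced training on a deterministic chain converges geometrically", {
  task <- build_observing_task(q = 1, trial_mixture = c(1, 0, 0))
  res <- engine_run(task, 50, alpha = 0.1, eng = eng_off(), seed = 1)
  v <- setNames(res$V, res$ct$ids)
  # CUE_LARGE is updated toward reward 1 on every trial: V_n = 1 - 0.9^n
  expect_equal(v[["CUE_LARGE"]], 1 - 0.9^50, tolerance = 1e-12)
  res2 <- engine_run(task, 400, alpha = 0.1, eng = eng_off(), seed = 1)
  expect_lt(abs(setNames(res2$V, res2$ct$ids)[["TGT_INFO"]] - 1), 0.01)
})

test_that("a disengaged trial records the re-engagement error at reward", {
  # a hazard pinned at 1 disengages on every trial at the target
  eng <- engagement_params(param_a = 1, param_b = 1e9, v_disengaged = 0)
  task <- build_observing_task(trial_mixture = c(0, 1, 0))
  out <- run_session(task, eng, n_trials = 30, seed = 6,
                     record_events = TRUE)
  ev <- out$events
  re <- ev[ev$state == "disengaged", ]
  expect_equal(nrow(re), 30)
  expect_false(any(re$engaged))
  expect_identical(re$event, rep("reward", 30))
  # delta = r - v_disengaged: larger than any engaged 50% prediction error
  trials <- out$trials
  expect_equal(re$delta, trials$reward)
  # disengagement recorded at the target, cue states never updated
  expect_true(all(trials$disengaged_at == "TGT_RAND"))
  expect_equal(out$values$values[["CUE_RAND_A"]], 0)
})

test_that("the acquisition trajectory rises from indifference toward its asymptote", {
  traj <- sapply(1:8, function(i) {
    run_acquisition(default_task(), n_sessions = 20, seed = 100 + i)$sessions$bias
  })
  m <- rowMeans(traj)
  fit <- stats::lm(m ~ seq_along(m))
  expect_gt(stats::coef(fit)[2], 0)
  expect_gt(mean(m[16:20]), mean(m[1:5]))
})
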