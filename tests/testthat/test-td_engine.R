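test_that("TD errors and updates follow the one-step rule without discount", {
  task <- default_task()
  V <- value_table(task)
  expect_equal(td_error(V, "CUE_LARGE", 1, "END"), 1)
  V$values[c("TGT_INFO", "CUE_LARGE")] <- 1
  expect_equal(td_error(V, "TGT_INFO", 0, "CUE_LARGE"), 0)
  V2 <- value_table(task, v0 = c(CUE_SMALL = 0.52))
  expect_equal(td_error(V2, "CUE_SMALL", 0.04, "END"), -0.48)
  expect_error(td_error(V, "NOPE", 0, "END"), "unknown state")

  # updates: V <- V + alpha * delta, other entries untouched
  V3 <- td_update(value_table(task), "TGT_INFO", 1, 0.1)
  expect_equal(V3$values[["TGT_INFO"]], 0.1)
  expect_true(all(V3$values[names(V3$values) != "TGT_INFO"] == 0))
  expect_identical(td_update(V3, "TGT_INFO", 0, 0.5)$values, V3$values)
  # alpha = 1 jumps straight to the target
  V4 <- value_table(task, v0 = 0.3)
  V4 <- td_update(V4, "CUE_LARGE", td_error(V4, "CUE_LARGE", 1, "END"), 1)
  expect_equal(V4$values[["CUE_LARGE"]], 1)
  expect_error(td_update(V4, "END", 1, 0.1), "terminal")
  expect_error(td_update(V4, "disengaged", 1, 0.1), "non-updating")
  expect_error(td_update(V4, "TGT_INFO", 1, 1.5), "alpha")
})

test_that("repeated disengagement decays a value geometrically to v_disengaged", {
  task <- default_task()
  for (vd in c(0, 0.3)) {
    V <- value_table(task, v0 = c(CUE_RAND_A = 0.52), v_disengaged = vd)
    expect_equal(td_error_disengaged(V, "CUE_RAND_A"), vd - 0.52)
    alpha <- 0.2
    for (k in 1:25) {
      V <- td_update(V, "CUE_RAND_A", td_error_disengaged(V, "CUE_RAND_A"),
                     alpha)
      # closed form: V_k = vd + (1 - alpha)^k * (V_0 - vd)
      expect_equal(V$values[["CUE_RAND_A"]],
                   vd + (1 - alpha)^k * (0.52 - vd), tolerance = 1e-12)
    }
    expect_equal(td_error_disengaged(
      value_table(task, v0 = c(TGT_INFO = vd), v_disengaged = vd),
      "TGT_INFO"), 0)
  }
})

test_that("re-engagement error is taken relative to the fixed state", {
  task <- default_task()
  V <- value_table(task, v_disengaged = 0)
  expect_equal(td_error_reengage(V, 1), 1)
  expect_equal(td_error_reengage(V, 0.04), 0.04)
  Vd <- value_table(task, v_disengaged = 0.3)
  expect_equal(td_error_reengage(Vd, 0.3), 0)
})

test_that("engaged prediction errors telescope to r - V(start)", {
  # with no disengagement every within-trial delta chains, so the trial sum
  # is exactly the reward minus the pre-trial value of the start state
  task <- default_task()
  eng <- eng_off()
  V <- value_table(task)
  set.seed(21)
  for (i in 1:40) {
    v_start <- V$values[["START"]]
    out <- run_trial(V, task, eng, policy_params(), alpha = 0.1)
    expect_equal(sum(out$errors$delta), out$record$reward - v_start,
                 tolerance = 1e-12)
    expect_true(all(out$errors$engaged))
    V <- out$values
  }
})

test_that("v_disengaged survives any amount of simulation unchanged", {
  task <- default_task()
  eng <- engagement_params(param_a = 0.3, v_disengaged = 0.25)
  out <- run_session(task, eng, n_trials = 500, seed = 4,
                     V = value_table(task, v_disengaged = 0.25))
  expect_identical(out$values$v_disengaged, 0.25)
  expect_equal(out$values$values[["END"]], 0)
})

test_that("dopamine_trace averages per event and rejects empty conditions", {
  task <- default_task()
  out <- run_session(task, engagement_params(), n_trials = 400, seed = 2,
                     record_events = TRUE)
  tr <- dopamine_trace(out$events, trial_type = "forced_informative")
  expect_setequal(tr$event, c("target", "cue", "reward"))
  expect_true(all(tr$n > 0))
  # single record: the trace is that record's delta
  one <- out$events[5, , drop = FALSE]
  tr1 <- dopamine_trace(one)
  expect_equal(tr1$mean_delta, one$delta)
  expect_error(dopamine_trace(out$events, trial_type = "no_such_type"),
               "no prediction-error records")
})

test_that("signal truncation floors negatives at the fraction of the peak", {
  tr <- c(2, -1, 0.5, -0.2, -10)
  out <- truncate_signal(tr)
  expect_equal(min(out), -0.25 * 2)
  expect_identical(out[tr >= -0.5], tr[tr >= -0.5])
  # identity when nothing falls below the floor
  expect_identical(truncate_signal(c(1, 0.2, 0)), c(1, 0.2, 0))
  expect_error(truncate_signal(c(-1, 0)), "no positive")
  # ratio property on arbitrary traces
  set.seed(8)
  for (i in 1:20) {
    x <- stats::rnorm(50)
    if (!any(x > 0)) next
    y <- truncate_signal(x)
    expect_gte(min(y) / max(y), -0.25 - 1e-12)
    expect_identical(y[x > 0], x[x > 0])
  }
})
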