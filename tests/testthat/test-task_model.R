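test_that("built task is valid and all pre-cue states expect q*rl + (1-q)*rs", {
  task <- default_task()
  expect_length(validate_task(task), 0)
  ex <- state_expectations(task)
  # 0.5 * 1 + 0.5 * 0.04 = 0.52 from every state before the cues
  for (s in c("START", "TGT_INFO", "TGT_RAND", "CHOICE",
              "CUE_RAND_A", "CUE_RAND_B")) {
    expect_equal(ex[[s]], 0.52, tolerance = 1e-12)
  }
  expect_equal(ex[["CUE_LARGE"]], 1)
  expect_equal(ex[["CUE_SMALL"]], 0.04)
  expect_equal(ex[["END"]], 0)

  # degenerate mixtures
  ex1 <- state_expectations(build_observing_task(q = 1))
  expect_equal(ex1[["TGT_INFO"]], 1)
  expect_equal(ex1[["CUE_RAND_A"]], 1)
  exq <- state_expectations(build_observing_task(r_large = 0.5,
                                                 r_small = 0.5))
  expect_true(all(abs(exq[c("CUE_LARGE", "CUE_SMALL", "CUE_RAND_A")] - 0.5)
                  < 1e-12))
})

test_that("path enumeration is a probability distribution with the right mean", {
  for (q in c(0.2, 0.5, 1)) {
    task <- build_observing_task(q = q)
    for (tt in c("forced_informative", "forced_random", "free_choice")) {
      pp <- enumerate_trial_paths(task, tt)
      expect_equal(sum(pp$prob), 1, tolerance = 1e-12)
      expect_equal(sum(pp$prob * pp$reward), q * 1 + (1 - q) * 0.04,
                   tolerance = 1e-12)
    }
  }
  # q = 1 makes CUE_SMALL unreachable on informative trials
  pp <- enumerate_trial_paths(build_observing_task(q = 1),
                              "forced_informative")
  expect_false(any(grepl("CUE_SMALL", pp$path)))
})

test_that("invalid constructor arguments name the offending field", {
  expect_error(build_observing_task(q = 1.5), "q")
  expect_error(build_observing_task(durations = c(TGT_INFO = -1)),
               "TGT_INFO")
  expect_error(build_observing_task(durations = c(NOPE = 1)), "NOPE")
  expect_error(build_observing_task(trial_mixture = c(0.5, 0.4, 0.2)),
               "trial_mixture")
})

test_that("validate_task reports each violation with the state and rule", {
  task <- default_task()
  bad <- task
  bad$states$TGT_INFO$successors$prob <- c(0.5, 0.4)
  v <- validate_task(bad)
  expect_length(v, 1)
  expect_match(v, "TGT_INFO")
  expect_match(v, "sum to 1")

  two_choice <- task
  two_choice$states$TGT_RAND$is_choice_state <- TRUE
  v <- validate_task(two_choice)
  expect_true(any(grepl("exactly one choice state", v)))

  # non-discriminative cues with differing reward statistics
  skew <- task
  skew$states$CUE_RAND_A$reward_on_exit$probs <- c(0.9, 0.1)
  v <- validate_task(skew)
  expect_true(any(grepl("reward distribution", v)))
})

test_that("reversal is an involution that only relabels contingencies", {
  for (variant in c("standard", "delayed")) {
    task <- build_observing_task(variant = variant)
    rev <- apply_reversal(task)
    expect_identical(variant_tag(rev), "reversed")
    # old informative target now leads to the non-discriminative branch
    expect_identical(sort(rev$states$TGT_INFO$successors$state_id),
                     sort(task$states$TGT_RAND$successors$state_id))
    # reward marginal is preserved (enumerate both trial trees)
    for (tt in c("forced_informative", "forced_random")) {
      pp <- enumerate_trial_paths(rev, tt)
      expect_equal(sum(pp$prob * pp$reward), 0.52, tolerance = 1e-12)
    }
    back <- apply_reversal(rev)
    expect_identical(back$states, task$states)
    expect_identical(variant_tag(back), variant)
  }
})

test_that("trial-type sampling follows the mixture and the seed", {
  task <- default_task()
  set.seed(11)
  draws <- sample_trial_type(task, n = 1e5)
  tab <- table(draws$label)
  chi <- suppressWarnings(
    stats::chisq.test(tab, p = rep(1 / 3, 3)))
  expect_gt(chi$p.value, 1e-3)
  # label determines the start state
  expect_true(all(draws$start_state[draws$label == "free_choice"] ==
                    "CHOICE"))

  only_info <- build_observing_task(trial_mixture = c(1, 0, 0))
  set.seed(1)
  expect_true(all(sample_trial_type(only_info, 100)$label ==
                    "forced_informative"))

  set.seed(42); a <- sample_trial_type(task, 1000)$label
  set.seed(42); b <- sample_trial_type(task, 1000)$label
  expect_identical(a, b)
})

test_that("task configs round-trip through YAML and JSON", {
  task <- build_observing_task(q = 0.3, variant = "delayed")
  eng <- engagement_params("salience", param_a = 0.2, param_b = 0.7)
  pol <- policy_params(beta = 3, rule = "softmax_log")
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_config(task, path, eng = eng, policy = pol)
    got <- read_config(path)
    expect_length(validate_task(got$task), 0)
    expect_equal(state_expectations(got$task), state_expectations(task))
    expect_identical(variant_tag(got$task), "delayed")
    expect_equal(got$engagement[c("hazard_family", "param_a", "param_b")],
                 eng[c("hazard_family", "param_a", "param_b")])
    expect_equal(got$policy$beta, 3)
    # identical simulation from the round-tripped task
    a <- run_session(task, eng, pol, n_trials = 100, seed = 9)$trials
    b <- run_session(got$task, got$engagement, got$policy,
                     n_trials = 100, seed = 9)$trials
    expect_identical(a, b)
  }
  # invalid documents are rejected with the violation listed
  bad <- withr::local_tempfile(fileext = ".json")
  doc <- observeTD:::.task_to_list(task)
  doc$states[[2]]$successors[[1]]$prob <- 0.9
  jsonlite::write_json(list(task = doc), bad, auto_unbox = TRUE)
  expect_error(read_config(bad), "sum to 1")
})

test_that("the shipped example config loads and validates", {
  path <- system.file("extdata", "observing-task.yaml",
                      package = "observeTD")
  got <- read_config(path)
  expect_length(validate_task(got$task), 0)
  expect_equal(state_expectations(got$task)[["CUE_RAND_A"]], 0.52)
  expect_equal(got$policy$beta, 10)
})
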