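# Simulation engine: compiles a task into integer-indexed arrays and runs the
# trial loop. The engine is the single code path behind run_trial(),
# run_session() and all experiment drivers, so a fixed seed yields an
# identical record stream whichever wrapper is used.

.compile_task <- function(task) {
  st <- task$states
  ids <- names(st)
  n <- length(ids)
  idx <- setNames(seq_len(n), ids)
  dur <- vapply(st, function(s) s$duration, numeric(1))
  is_term <- vapply(st, function(s) s$is_terminal, logical(1))
  is_choice <- vapply(st, function(s) s$is_choice_state, logical(1))
  nsucc <- integer(n); succ1 <- integer(n); succ2 <- integer(n)
  p1 <- numeric(n)
  rew_hi <- numeric(n); rew_lo <- numeric(n); rew_p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- st[[i]]
    if (is.data.frame(s$successors) && nrow(s$successors)) {
      k <- unname(idx[s$successors$state_id])
      nsucc[i] <- length(k)
      succ1[i] <- k[1]
      if (length(k) > 1L) succ2[i] <- k[2]
      p1[i] <- s$successors$prob[1]
    }
    if (!is.null(s$reward_on_exit)) {
      v <- s$reward_on_exit$values
      p <- s$reward_on_exit$probs
      rew_hi[i] <- v[1]
      rew_lo[i] <- if (length(v) > 1L) v[2] else v[1]
      rew_p[i] <- p[1]
    }
  }
  choice <- which(is_choice)
  cs <- st[[choice]]$successors$state_id
  tt <- task$trial_types
  # event label attached to the TD error generated on exiting each state
  exit_ev <- integer(n)
  for (i in seq_len(n)) {
    if (is_term[i]) next
    exit_ev[i] <- if (ids[i] == "START" || is_choice[i]) 1L
      else if (!is.na(rew_p[i])) 3L else 2L
  }
  list(
    n = n, ids = ids, idx = idx, dur = dur,
    is_term = is_term, is_choice = is_choice,
    nsucc = nsucc, succ1 = succ1, succ2 = succ2, p1 = p1,
    rew_hi = rew_hi, rew_lo = rew_lo, rew_p = rew_p,
    start = unname(idx[["START"]]),
    choice = choice,
    opt1 = unname(idx[[cs[1]]]), opt2 = unname(idx[[cs[2]]]),
    type_start = unname(idx[tt$start_state]),
    mix = tt$prob,
    # hazard applies to within-trial states except the choice moment and the
    # trial-start state (trial initiation re-engages, so no hazard accrues
    # before the target)
    elig = !is_term & !is_choice & ids != "START",
    exit_ev = exit_ev,
    r_large = task$r_large
  )
}

.EV_LABELS <- c("target", "cue", "reward")
.N_DRAWS <- 8L   # upper bound on uniform draws consumed per trial

.sim_engine <- function(ct, V, v_d, alpha, eng, pol, n_trials,
                        record_events = FALSE, vbar_burn = NULL) {
  sal <- eng$hazard_family == "salience"
  hz_fn <- eng$hazard_fn
  a <- eng$param_a; b <- eng$param_b
  beta <- pol$beta
  logrule <- pol$rule == "softmax_log"
  mix1 <- ct$mix[1]; mix12 <- ct$mix[1] + ct$mix[2]
  start <- ct$start; o1 <- ct$opt1; o2 <- ct$opt2
  dur <- ct$dur; elig <- ct$elig; is_term <- ct$is_term
  is_choice <- ct$is_choice; nsucc <- ct$nsucc
  succ1 <- ct$succ1; succ2 <- ct$succ2; p1 <- ct$p1
  rew_p <- ct$rew_p; rew_hi <- ct$rew_hi; rew_lo <- ct$rew_lo
  exit_ev <- ct$exit_ev; type_start <- ct$type_start

  U <- runif(n_trials * .N_DRAWS)

  t_type <- integer(n_trials); t_choice <- integer(n_trials)
  t_cue <- integer(n_trials); t_rew <- numeric(n_trials)
  t_dis <- integer(n_trials)
  if (record_events) {
    cap <- n_trials * 6L
    e_tr <- integer(cap); e_ev <- integer(cap); e_st <- integer(cap)
    e_d <- numeric(cap); e_en <- logical(cap)
  }
  m <- 0L
  vsum <- numeric(length(V)); vn <- 0L

  for (t in seq_len(n_trials)) {
    ub <- (t - 1L) * .N_DRAWS
    ui <- 1L
    x <- U[ub + ui]; ui <- ui + 1L
    tt <- if (x < mix1) 1L else if (x < mix12) 2L else 3L
    s <- type_start[tt]
    # target (or target-pair) onset: TD error updating the trial-start state
    d <- V[s] - V[start]
    V[start] <- V[start] + alpha * d
    if (record_events) {
      m <- m + 1L
      e_tr[m] <- t; e_ev[m] <- 1L; e_st[m] <- start; e_d[m] <- d
      e_en[m] <- TRUE
    }
    engaged <- TRUE; ds <- 0L; ch <- 0L; cue <- 0L; r <- 0
    repeat {
      if (is_choice[s]) {
        dv <- if (logrule) {
          beta * (log(max(V[o1], 1e-6)) - log(max(V[o2], 1e-6)))
        } else {
          beta * (V[o1] - V[o2])
        }
        pinfo <- 1 / (1 + exp(-dv))
        ch <- if (U[ub + ui] < pinfo) 1L else 2L
        ui <- ui + 1L
        nxt <- if (ch == 1L) o1 else o2
        if (engaged) {
          d <- V[nxt] - V[s]
          V[s] <- V[s] + alpha * d
          if (record_events) {
            m <- m + 1L
            e_tr[m] <- t; e_ev[m] <- 1L; e_st[m] <- s; e_d[m] <- d
            e_en[m] <- TRUE
          }
        }
        s <- nxt
        next
      }
      if (engaged && elig[s]) {
        v <- V[s]
        xv <- if (sal) abs(v) else v
        rho <- if (is.null(hz_fn)) a * exp(-xv / b) else hz_fn(xv)
        if (rho > 1) rho <- 1 else if (rho < 0) rho <- 0
        pdis <- 1 - (1 - rho)^dur[s]
        hit <- U[ub + ui] < pdis
        ui <- ui + 1L
        if (hit) {
          d <- v_d - V[s]
          V[s] <- V[s] + alpha * d
          if (record_events) {
            m <- m + 1L
            e_tr[m] <- t; e_ev[m] <- exit_ev[s]; e_st[m] <- s; e_d[m] <- d
            e_en[m] <- FALSE
          }
          engaged <- FALSE
          ds <- s
        }
      }
      if (nsucc[s] == 1L) {
        nxt <- succ1[s]
      } else {
        nxt <- if (U[ub + ui] < p1[s]) succ1[s] else succ2[s]
        ui <- ui + 1L
      }
      if (is_term[nxt]) {
        if (!is.na(rew_p[s])) {
          r <- if (U[ub + ui] < rew_p[s]) rew_hi[s] else rew_lo[s]
          ui <- ui + 1L
        }
        cue <- s
        if (engaged) {
          d <- r - V[s]
          V[s] <- V[s] + alpha * d
          if (record_events) {
            m <- m + 1L
            e_tr[m] <- t; e_ev[m] <- 3L; e_st[m] <- s; e_d[m] <- d
            e_en[m] <- TRUE
          }
        } else {
          # re-engagement at reward: TD error relative to the fixed state;
          # updates nothing (the disengaged state is non-updating)
          d <- r - v_d
          if (record_events) {
            m <- m + 1L
            e_tr[m] <- t; e_ev[m] <- 3L; e_st[m] <- 0L; e_d[m] <- d
            e_en[m] <- FALSE
          }
        }
        break
      } else {
        if (engaged) {
          d <- V[nxt] - V[s]
          V[s] <- V[s] + alpha * d
          if (record_events) {
            m <- m + 1L
            e_tr[m] <- t; e_ev[m] <- exit_ev[s]; e_st[m] <- s; e_d[m] <- d
            e_en[m] <- TRUE
          }
        }
        s <- nxt
      }
    }
    t_type[t] <- tt; t_choice[t] <- ch; t_cue[t] <- cue
    t_rew[t] <- r; t_dis[t] <- ds
    if (!is.null(vbar_burn) && t > vbar_burn) {
      vsum <- vsum + V
      vn <- vn + 1L
    }
  }

  out <- list(V = V, type = t_type, choice = t_choice, cue = t_cue,
              reward = t_rew, dis = t_dis)
  if (!is.null(vbar_burn)) out$vbar <- vsum / max(vn, 1L)
  if (record_events) {
    out$events <- list(trial = e_tr[seq_len(m)], ev = e_ev[seq_len(m)],
                       state = e_st[seq_len(m)], delta = e_d[seq_len(m)],
                       engaged = e_en[seq_len(m)])
  }
  out
}

.trials_df <- function(ct, res, offset = 0L) {
  data.frame(
    trial_index = seq_along(res$type) + offset,
    trial_type = .trial_type_labels[res$type],
    chosen_option = c("none", "informative", "random")[
      ifelse(res$type == 3L, res$choice + 1L, 1L)],
    cue_shown = ct$ids[res$cue],
    reward = res$reward,
    outcome = ifelse(res$reward == ct$r_large, "large", "small"),
    disengaged_at = ifelse(res$dis > 0L, ct$ids[pmax(res$dis, 1L)],
                           NA_character_),
    stringsAsFactors = FALSE
  )
}

.events_df <- function(ct, res, offset = 0L) {
  if (is.null(res$events)) return(NULL)
  e <- res$events
  data.frame(
    trial = e$trial + offset,
    event = .EV_LABELS[e$ev],
    state = ifelse(e$state > 0L, ct$ids[pmax(e$state, 1L)], "disengaged"),
    delta = e$delta,
    engaged = e$engaged,
    trial_type = .trial_type_labels[res$type[e$trial]],
    outcome = ifelse(res$reward[e$trial] == ct$r_large, "large", "small"),
    stringsAsFactors = FALSE
  )
}

.check_vd <- function(V, eng) {
  if (!isTRUE(all.equal(V$v_disengaged, eng$v_disengaged))) {
    stop("value_table and engagement_params disagree on v_disengaged",
         call. = FALSE)
  }
}

#' Simulate one trial
#'
#' Samples a trial type, walks the state path while applying TD updates, and
#' draws the engagement outcome for each hazard-eligible state. On
#' disengagement the current state is updated toward the disengaged-state
#' value, no further state is updated until the reward, and the
#' re-engagement TD error is recorded at reward delivery. On free-choice
#' trials the branch is drawn from the softmax on the current values. Uses
#' R's global random number stream.
#'
#' @param V A [value_table()].
#' @param task An [build_observing_task()] task.
#' @param eng An [engagement_params()] object.
#' @param policy A [policy_params()] object.
#' @param alpha Learning rate in `(0, 1]`.
#' @return A list with `record` (one-row trial `data.frame`), `errors` (the
#'   trial's time-stamped prediction errors), and `values` (the updated
#'   `value_table`).
#' @export
run_trial <- function(V, task, eng, policy = policy_params(), alpha = 0.1) {
  stopifnot(inherits(V, "value_table"), inherits(task, "observing_task"))
  .check_vd(V, eng)
  ct <- .compile_task(task)
  res <- .sim_engine(ct, unname(V$values[ct$ids]), V$v_disengaged, alpha,
                     eng, policy, 1L, record_events = TRUE)
  V$values[ct$ids] <- res$V
  list(record = .trials_df(ct, res),
       errors = .events_df(ct, res),
       values = V)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' The exact interval via beta-distribution quantiles, used to band the
#' per-session observing bias. By convention the lower bound is exactly 0
#' when `k = 0` and the upper bound exactly 1 when `k = n`.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `>= 1`.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
clopper_pearson <- function(k, n, conf = 0.95) {
  if (!is.numeric(k) || !is.numeric(n) || length(k) != 1L ||
      length(n) != 1L || is.na(k) || is.na(n) || n < 1 || k < 0 || k > n ||
      k != round(k) || n != round(n)) {
    stop("clopper_pearson: need integers 0 <= k <= n with n >= 1",
         call. = FALSE)
  }
  a <- (1 - conf) / 2
  low <- if (k == 0) 0 else qbeta(a, k, n - k + 1)
  high <- if (k == n) 1 else qbeta(1 - a, k + 1, n - k)
  c(low = low, high = high)
}

.session_summary <- function(trials, session_index = 1L, conf = 0.95) {
  ch <- trials$trial_type == "free_choice"
  n_choice <- sum(ch)
  n_info <- sum(trials$chosen_option[ch] == "informative")
  if (n_choice == 0L) {
    return(data.frame(session = session_index, n_choice = 0L, n_info = 0L,
                      bias = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      undefined_bias = TRUE))
  }
  ci <- clopper_pearson(n_info, n_choice, conf)
  data.frame(session = session_index, n_choice = n_choice, n_info = n_info,
             bias = n_info / n_choice, ci_low = ci[["low"]],
             ci_high = ci[["high"]], undefined_bias = FALSE)
}

#' Simulate one session
#'
#' Runs `n_trials` trials with carried-over values and summarizes the
#' session's observing bias (fraction of free-choice trials on which the
#' discriminative option was chosen) with its exact Clopper-Pearson
#' confidence interval. Sessions with no choice trials return an `NA` bias
#' flagged by `undefined_bias`.
#'
#' @inheritParams run_trial
#' @param n_trials Trials per session (default 480, which yields 160
#'   free-choice trials in expectation under the default mixture).
#' @param seed Optional integer seed (sets R's RNG before the session).
#' @param record_events Record the per-event prediction errors (off by
#'   default for volume).
#' @param session_index Index stored in the summary row.
#' @return A list with `trials`, `summary`, `values`, and (optionally)
#'   `events`.
#' @export
run_session <- function(task, eng = engagement_params(),
                        policy = policy_params(), n_trials = 480,
                        V = NULL, alpha = 0.1, seed = NULL,
                        record_events = FALSE, session_index = 1L) {
  stopifnot(n_trials >= 1)
  if (is.null(V)) V <- value_table(task, v_disengaged = eng$v_disengaged)
  .check_vd(V, eng)
  if (!is.null(seed)) set.seed(seed)
  ct <- .compile_task(task)
  res <- .sim_engine(ct, unname(V$values[ct$ids]), V$v_disengaged, alpha,
                     eng, policy, as.integer(n_trials),
                     record_events = record_events)
  V$values[ct$ids] <- res$V
  trials <- .trials_df(ct, res)
  list(trials = trials,
       summary = .session_summary(trials, session_index),
       values = V,
       events = .events_df(ct, res))
}

# Per-session seeds derived from a master seed via a counter scheme, so any
# session of a run can be reproduced in isolation. Constants are arbitrary
# primes; results stay below 2^31 - 1.
.session_seed <- function(master, k) {
  as.integer((as.double(master) * 48271 + as.double(k) * 16807) %%
               2147483647) + 1L
}

.run_sessions <- function(task, eng, policy, n_sessions, n_trials, alpha,
                          v0, seed, record_events = FALSE,
                          reverse_at = NULL, keep_trials = FALSE) {
  V <- value_table(task, v0 = v0, v_disengaged = eng$v_disengaged)
  sessions <- vector("list", n_sessions)
  trials <- if (keep_trials) vector("list", n_sessions) else NULL
  events <- if (record_events) vector("list", n_sessions) else NULL
  for (k in seq_len(n_sessions)) {
    if (!is.null(reverse_at) && k == reverse_at) task <- apply_reversal(task)
    out <- run_session(task, eng, policy, n_trials = n_trials, V = V,
                       alpha = alpha, seed = .session_seed(seed, k),
                       record_events = record_events, session_index = k)
    V <- out$values
    sessions[[k]] <- out$summary
    if (keep_trials) {
      out$trials$session <- k
      trials[[k]] <- out$trials
    }
    if (record_events) {
      out$events$session <- k
      events[[k]] <- out$events
    }
  }
  structure(
    list(sessions = do.call(rbind, sessions),
         values = V,
         trials = if (keep_trials) do.call(rbind, trials) else NULL,
         events = if (record_events) do.call(rbind, events) else NULL,
         task = task, eng = eng, policy = policy,
         alpha = alpha, seed = seed, n_trials = n_trials),
    class = "observing_run"
  )
}

#' @export
print.observing_run <- function(x, ...) {
  ns <- nrow(x$sessions)
  late <- x$sessions[x$sessions$session > ns - min(5L, ns), , drop = FALSE]
  cat("<observing_run>", ns, "sessions x", x$n_trials, "trials |",
      "task:", variant_tag(x$task), "| beta =", x$policy$beta, "\n")
  cat(sprintf("  mean bias, last %d sessions: %.3f\n", nrow(late),
              mean(late$bias, na.rm = TRUE)))
  invisible(x)
}

#' Acquisition of the observing bias over sessions
#'
#' Simulates learning from fresh values over `n_sessions` sessions of
#' `n_trials` trials each, with values carried across sessions, and returns
#' the per-session observing bias with Clopper-Pearson confidence intervals.
#' With disengagement on and a reasonably large `beta`, the bias rises
#' gradually from about 0.5 toward its asymptote over many sessions.
#'
#' @inheritParams run_session
#' @param n_sessions Number of sessions (default 25).
#' @param v0 Initial value of all non-terminal states.
#' @param seed Master seed; per-session seeds are derived from it.
#' @param keep_trials Keep the full trial log.
#' @return An `observing_run` object with elements `sessions` (data.frame),
#'   `values`, and optionally `trials`/`events`.
#' @export
run_acquisition <- function(task = build_observing_task(),
                            eng = engagement_params(),
                            policy = policy_params(),
                            n_sessions = 25, n_trials = 480, alpha = 0.1,
                            v0 = 0, seed = 1, record_events = FALSE,
                            keep_trials = FALSE) {
  .run_sessions(task, eng, policy, n_sessions, n_trials, alpha, v0, seed,
                record_events = record_events, keep_trials = keep_trials)
}

#' Reversal of the observing contingencies mid-run
#'
#' As [run_acquisition()], but at the start of session `switch_session` the
#' target-branch contingencies are reversed (see [apply_reversal()]) without
#' resetting the learned values. The bias trajectory, defined throughout as
#' the fraction of choices of the originally discriminative target, then
#' crosses 0.5 and approaches the reversed asymptote at the slow pace set by
#' the smallness of the disengagement bias.
#'
#' @inheritParams run_acquisition
#' @param switch_session Session index at whose start the reversal is
#'   applied.
#' @return An `observing_run`; its `sessions` table gains a `phase` column
#'   (`"pre"`/`"post"`).
#' @export
run_reversal <- function(task = build_observing_task(variant = "delayed"),
                         eng = engagement_params(),
                         policy = policy_params(),
                         switch_session = 9, n_sessions = 24,
                         n_trials = 480, alpha = 0.1, v0 = 0, seed = 1,
                         record_events = FALSE) {
  stopifnot(switch_session >= 1, switch_session <= n_sessions)
  run <- .run_sessions(task, eng, policy, n_sessions, n_trials, alpha, v0,
                       seed, record_events = record_events,
                       reverse_at = switch_session)
  run$sessions$phase <- ifelse(run$sessions$session < switch_session,
                               "pre", "post")
  run$switch_session <- switch_session
  run
}

#' Asymptotic observing bias for an aversive task
#'
#' Runs acquisition on a task with negative reward values (punishments)
#' under the chosen hazard family and returns the asymptotic bias per seed
#' (pooled over the last `last_k` sessions). A salience (symmetric) hazard
#' protects engagement for large-punishment predictions, so disengagement
#' inflates the subjective value of the non-discriminative cues and subjects
#' prefer the random option (bias below 0.5); the valence (asymmetric)
#' hazard instead yields more observing.
#'
#' @inheritParams run_acquisition
#' @param hazard_family `"valence"` or `"salience"`.
#' @param n_seeds Number of independent runs.
#' @param n_sessions,last_k Sessions per run and number of final sessions
#'   pooled for the asymptotic bias.
#' @param q,r_large,r_small Aversive task parameters (defaults: 50% chance
#'   of a large, `-1`, vs small, `-0.04`, punishment).
#' @return A `data.frame` with one row per seed: `seed`, `hazard_family`,
#'   `n_choice`, `bias`.
#' @export
run_aversive <- function(hazard_family = c("valence", "salience"),
                         n_seeds = 20, n_sessions = 15, last_k = 5,
                         q = 0.5, r_large = -1, r_small = -0.04,
                         eng = NULL, policy = policy_params(),
                         n_trials = 480, alpha = 0.1, seed = 1) {
  hazard_family <- match.arg(hazard_family)
  if (is.null(eng)) eng <- engagement_params(hazard_family = hazard_family)
  task <- build_observing_task(q = q, r_large = r_large, r_small = r_small)
  out <- lapply(seq_len(n_seeds), function(i) {
    run <- .run_sessions(task, eng, policy, n_sessions, n_trials, alpha,
                         v0 = 0, seed = .session_seed(seed, 1000L + i))
    late <- run$sessions[run$sessions$session > n_sessions - last_k, ]
    data.frame(seed = i, hazard_family = hazard_family,
               n_choice = sum(late$n_choice),
               bias = sum(late$n_info) / sum(late$n_choice))
  })
  do.call(rbind, out)
}

#' Transient observing bias induced by the initial values
#'
#' Because the disengagement bias is small and develops slowly, the early
#' course of learning is dominated by the initial values. Starting far below
#' the true values (with a rich reward schedule) puts the system in the
#' high-hazard region early on, transiently exaggerating the bias
#' (over-observation); starting far above the true values (with a thin
#' schedule) suppresses disengagement early, so the bias starts below its
#' long-run level (under-observation). The default learning rate here is
#' smaller than elsewhere so the transient spans several sessions at session
#' resolution.
#'
#' @inheritParams run_acquisition
#' @param v0 Initial value of all non-terminal states.
#' @param q Probability of the large reward.
#' @param n_seeds Number of independent runs (rows are stacked).
#' @return A `data.frame` of per-session summaries with `seed` and `q`
#'   columns.
#' @export
run_initial_values <- function(v0, q, n_sessions = 40, n_seeds = 1,
                               eng = engagement_params(),
                               policy = policy_params(),
                               n_trials = 480, alpha = 0.01, seed = 1) {
  task <- build_observing_task(q = q)
  out <- lapply(seq_len(n_seeds), function(i) {
    run <- .run_sessions(task, eng, policy, n_sessions, n_trials, alpha,
                         v0 = v0, seed = .session_seed(seed, 2000L + i))
    cbind(seed = i, q = q, v0 = v0, run$sessions)
  })
  do.call(rbind, out)
}
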