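# Asymptotic (self-consistent) values under disengagement. At stationarity
# the expected TD update of every state is zero, which gives the coupled
# system
#   V(s) = (1 - p_dis(V(s))) * E[r + V(s')] + p_dis(V(s)) * v_disengaged
# for hazard-eligible states, the plain expectation for the others, and a
# choice-state expectation weighted by the softmax of the current iterate.
# The system is solved by damped fixed-point iteration.

.backup <- function(ct, V, v_d, eng, pol, clamp_log = TRUE) {
  out <- V
  for (i in seq_len(ct$n)) {
    if (ct$is_term[i]) {
      out[i] <- 0
      next
    }
    if (ct$is_choice[i]) {
      o1 <- ct$opt1; o2 <- ct$opt2
      p <- if (pol$rule == "softmax_log" && clamp_log) {
        plogis(pol$beta * (log(max(V[o1], 1e-6)) - log(max(V[o2], 1e-6))))
      } else {
        choice_prob(V[o1], V[o2], pol)
      }
      out[i] <- p * V[o1] + (1 - p) * V[o2]
      next
    }
    succ <- if (ct$nsucc[i] == 1L) ct$succ1[i] else c(ct$succ1[i], ct$succ2[i])
    pr <- if (ct$nsucc[i] == 1L) 1 else c(ct$p1[i], 1 - ct$p1[i])
    if (ct$ids[i] == "START") pr <- ct$mix
    if (ct$ids[i] == "START") succ <- ct$type_start
    rbar <- if (is.na(ct$rew_p[i])) 0 else {
      ct$rew_p[i] * ct$rew_hi[i] + (1 - ct$rew_p[i]) * ct$rew_lo[i]
    }
    ex <- rbar + sum(pr * V[succ])
    if (ct$elig[i]) {
      pd <- p_disengage_state(disengage_hazard(V[i], eng), ct$dur[i])
      out[i] <- (1 - pd) * ex + pd * v_d
    } else {
      out[i] <- ex
    }
  }
  out
}

#' Solve the self-consistent asymptotic values under disengagement
#'
#' Damped fixed-point iteration on the stationarity equations of the TD
#' model with value-dependent disengagement: each state's asymptotic value
#' is its expected backup in which, with the state's own disengagement
#' probability, the successor value is replaced by the disengaged-state
#' value; the choice-state expectation weights the two branches by the
#' softmax of the current iterate. With the hazard switched off the solution
#' equals the closed-form expectations of [state_expectations()].
#'
#' To flag non-uniqueness, the iteration is restarted from `n_starts` random
#' initializations (plus the true expectations); all distinct solutions are
#' reported.
#'
#' @param task An [build_observing_task()] task.
#' @param eng An [engagement_params()] object.
#' @param policy A [policy_params()] object.
#' @param tol Convergence tolerance on the undamped residual
#'   `max |backup(V) - V|`.
#' @param max_iter Iteration cap; exceeding it is an error carrying the
#'   final residual.
#' @param damping Damping factor `gamma` of the update
#'   `V <- (1 - gamma) V + gamma backup(V)`; the converged solution is
#'   independent of it.
#' @param n_starts Number of additional random initializations.
#' @return A `fixed_point_result`: `values` (named vector), `bias`
#'   (asymptotic probability of choosing the discriminative option),
#'   `iterations`, `residual`, and `all_solutions` (a matrix with one row
#'   per distinct solution found).
#' @export
solve_self_consistent <- function(task, eng = engagement_params(),
                                  policy = policy_params(),
                                  tol = 1e-10, max_iter = 1e5,
                                  damping = 0.5, n_starts = 5) {
  stopifnot(tol > 0, damping > 0, damping <= 1)
  ct <- .compile_task(task)
  v_d <- eng$v_disengaged
  scale <- max(abs(c(task$r_large, task$r_small, v_d, 1)))

  iterate <- function(V) {
    it <- 0L
    repeat {
      B <- .backup(ct, V, v_d, eng, policy)
      res <- max(abs(B - V))
      if (res < tol) return(list(V = B, iterations = it, residual = res))
      V <- (1 - damping) * V + damping * B
      it <- it + 1L
      if (it >= max_iter) {
        stop(sprintf(paste(
          "solve_self_consistent: no convergence after %d iterations",
          "(residual %.3g); a smaller damping factor may help"),
          it, res), call. = FALSE)
      }
    }
  }

  V0 <- unname(state_expectations(task)[ct$ids])
  main <- iterate(V0)
  sols <- matrix(main$V, nrow = 1)
  if (n_starts > 0) {
    starts <- matrix(runif(n_starts * ct$n, min = min(0, -scale),
                           max = scale), nrow = n_starts)
    for (k in seq_len(n_starts)) {
      s <- iterate(starts[k, ])
      if (all(abs(s$V - sols[1, ]) < 1e-6) ||
          any(apply(sols, 1, function(x) max(abs(x - s$V)) < 1e-6))) next
      sols <- rbind(sols, s$V)
    }
  }
  if (nrow(sols) > 1) {
    warning("solve_self_consistent: multiple distinct fixed points found; ",
            "returning the one seeded from the true expectations",
            call. = FALSE)
  }
  vals <- setNames(main$V, ct$ids)
  bias <- if (policy$rule == "softmax_log") {
    plogis(policy$beta * (log(max(vals[[ct$ids[ct$opt1]]], 1e-6)) -
                            log(max(vals[[ct$ids[ct$opt2]]], 1e-6))))
  } else {
    choice_prob(vals[[ct$ids[ct$opt1]]], vals[[ct$ids[ct$opt2]]], policy)
  }
  structure(list(values = vals, bias = unname(bias),
                 iterations = main$iterations, residual = main$residual,
                 all_solutions = sols),
            class = "fixed_point_result")
}

#' @export
print.fixed_point_result <- function(x, ...) {
  cat("<fixed_point_result> bias =", round(x$bias, 4),
      "| iterations =", x$iterations,
      "| residual =", format(x$residual, digits = 3), "\n")
  print(round(x$values, 4))
  invisible(x)
}

#' Asymptotic observing bias as a function of reward probability
#'
#' Solves the fixed point at each reward probability `q` for the
#' difference-based and the log-value (ratio-based) softmax and returns the
#' paired bias curves. Under the difference rule the bias peaks between the
#' extremes and is asymmetric about `q = 0.5`; under the log rule the bias
#' keeps increasing as the reward schedule thins (`q` small), matching the
#' observation that animals observe more even as the information gained
#' decreases.
#'
#' @param q_grid Reward probabilities in `(0, 1)`.
#' @param eng An [engagement_params()] object.
#' @param beta Inverse temperature used for both rules.
#' @param rules Which choice rules to evaluate.
#' @param r_large,r_small Reward magnitudes.
#' @param ... Passed on to [solve_self_consistent()].
#' @return A `data.frame` with columns `q`, `rule`, `bias`.
#' @export
bias_vs_reward_prob <- function(q_grid, eng = engagement_params(),
                                beta = 10,
                                rules = c("softmax_difference",
                                          "softmax_log"),
                                r_large = 1, r_small = 0.04, ...) {
  stopifnot(all(q_grid > 0 & q_grid < 1))
  out <- list()
  for (rule in rules) {
    pol <- policy_params(beta = beta, rule = rule)
    for (q in q_grid) {
      fp <- tryCatch(
        solve_self_consistent(
          build_observing_task(q = q, r_large = r_large, r_small = r_small),
          eng, pol, ...),
        error = function(e) {
          stop("bias_vs_reward_prob failed at q = ", q, " (", rule, "): ",
               conditionMessage(e), call. = FALSE)
        })
      out[[length(out) + 1L]] <- data.frame(q = q, rule = rule,
                                            bias = fp$bias)
    }
  }
  do.call(rbind, out)
}
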