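#' Create a value table for a task
#'
#' Holds the learned value `V(s)` of every state in reward units plus the
#' fixed value of the disengaged state. The terminal state is pinned at 0 and
#' never updated; the disengaged-state value is a fixed parameter that no
#' update may modify.
#'
#' @param task An `observing_task`.
#' @param v0 Initial value assigned to all non-terminal states (scalar, or a
#'   named vector of per-state initial values).
#' @param v_disengaged Fixed value of the disengaged state.
#' @return A `value_table` object.
#' @export
value_table <- function(task, v0 = 0, v_disengaged = 0) {
  ids <- names(task$states)
  term <- vapply(task$states, function(s) s$is_terminal, logical(1))
  vals <- setNames(rep(0, length(ids)), ids)
  if (length(v0) == 1L && is.null(names(v0))) {
    vals[!term] <- v0
  } else {
    stopifnot(all(names(v0) %in% ids))
    vals[names(v0)] <- v0
    vals[term] <- 0
  }
  if (any(!is.finite(vals)) || !is.finite(v_disengaged)) {
    stop("value_table: all values must be finite", call. = FALSE)
  }
  structure(list(values = vals, v_disengaged = v_disengaged,
                 terminal = ids[term]),
            class = "value_table")
}

#' @export
print.value_table <- function(x, ...) {
  cat("<value_table> v_disengaged =", x$v_disengaged, "\n")
  print(round(x$values, 4))
  invisible(x)
}

.check_state <- function(V, s) {
  if (!s %in% names(V$values)) {
    stop("unknown state '", s, "' in value table", call. = FALSE)
  }
}

#' Temporal-difference error for an engaged transition
#'
#' The one-step TD error `delta = r + V(s_next) - V(s)` for the transition
#' `s -> s_next` that delivers reward `r`. No within-trial discounting is
#' applied; the terminal state has value 0, so the reward event of a trial
#' yields `delta = r - V(cue)`.
#'
#' @param V A `value_table`.
#' @param s Source state id.
#' @param r Delivered reward in reward units (0 except on entering the
#'   terminal state).
#' @param s_next Successor state id.
#' @return The TD error, a numeric scalar in reward units.
#' @export
td_error <- function(V, s, r, s_next) {
  .check_state(V, s); .check_state(V, s_next)
  r + V$values[[s_next]] - V$values[[s]]
}

#' Apply a TD update to one state
#'
#' `V(s) <- V(s) + alpha * delta`. The terminal state and the disengaged
#' state are non-updating; attempting to update them is a contract violation.
#' Learning proceeds on all three trial types.
#'
#' @param V A `value_table`.
#' @param s State id to update.
#' @param delta TD error.
#' @param alpha Learning rate in `(0, 1]`.
#' @return The updated `value_table`.
#' @export
td_update <- function(V, s, delta, alpha) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  if (identical(s, "disengaged")) {
    stop("the disengaged state is non-updating", call. = FALSE)
  }
  .check_state(V, s)
  if (s %in% V$terminal) {
    stop("state '", s, "' is terminal and non-updating", call. = FALSE)
  }
  V$values[[s]] <- V$values[[s]] + alpha * delta
  V
}

#' TD error on disengagement
#'
#' When engagement is lost during state `s`, the successor becomes the fixed
#' disengaged state and no reward accompanies the transition, so the update
#' signal for `s` is `delta = v_disengaged - V(s)`. Applied to `s` via
#' [td_update()], repeated disengagement therefore drives `V(s)` toward
#' `v_disengaged` geometrically; this is the source of the negative bias on
#' low-value, frequently-disengaged states.
#'
#' @inheritParams td_error
#' @return The disengagement TD error.
#' @export
td_error_disengaged <- function(V, s) {
  .check_state(V, s)
  V$v_disengaged - V$values[[s]]
}

#' TD error at re-engagement
#'
#' A disengaged system is re-engaged by reward delivery at the end of the
#' trial, creating a TD error relative to the fixed state:
#' `delta = r - v_disengaged`. Because the disengaged state is non-updating,
#' this error is recorded for the modeled dopamine signal but trains no state
#' value. After disengagement on a non-discriminative trial, delivery of the
#' large reward thus elicits a response larger than the one expected from a
#' 50% prediction.
#'
#' @inheritParams td_error
#' @return The re-engagement TD error.
#' @export
td_error_reengage <- function(V, r) {
  r - V$v_disengaged
}

#' Mean modeled dopamine signal per trial event
#'
#' Averages the recorded TD errors at the target, cue, and reward events over
#' the trials matching a condition (trial type and/or outcome), across both
#' engaged and disengaged trials. The TD error is the model's stand-in for
#' phasic dopamine activity.
#'
#' @param events A prediction-error record as produced by the simulation
#'   functions: a `data.frame` with columns `trial`, `event`, `state`,
#'   `delta`, `engaged`, `trial_type`, `outcome`.
#' @param trial_type Optional filter: one of `"forced_informative"`,
#'   `"forced_random"`, `"free_choice"`.
#' @param outcome Optional filter: `"large"` or `"small"`.
#' @return A `data.frame` with one row per event (`target`, `cue`, `reward`)
#'   holding the mean `delta` and the number of contributing records.
#' @export
dopamine_trace <- function(events, trial_type = NULL, outcome = NULL) {
  stopifnot(is.data.frame(events),
            all(c("event", "delta") %in% names(events)))
  keep <- rep(TRUE, nrow(events))
  if (!is.null(trial_type)) keep <- keep & events$trial_type %in% trial_type
  if (!is.null(outcome)) keep <- keep & events$outcome %in% outcome
  ev <- events[keep, , drop = FALSE]
  if (!nrow(ev)) {
    stop("dopamine_trace: no prediction-error records match the condition",
         call. = FALSE)
  }
  labs <- c("target", "cue", "reward")
  labs <- labs[labs %in% ev$event]
  out <- data.frame(
    event = labs,
    mean_delta = vapply(labs, function(l) mean(ev$delta[ev$event == l]),
                        numeric(1)),
    n = vapply(labs, function(l) sum(ev$event == l), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Truncate negative responses of a modeled dopamine trace
#'
#' Dopamine neurons have less dynamic range for decreases than increases in
#' firing rate, so for presentation the negative part of the modeled TD
#' signal is floored at `-floor_fraction` times the maximal positive
#' response. Values below the floor are replaced by exactly the floor;
#' positive values are untouched. This convention is used for display only
#' and never enters learning.
#'
#' @param trace Numeric vector of TD errors.
#' @param floor_fraction Fraction of the maximal positive response at which
#'   to floor negative values (default 0.25).
#' @return The truncated trace.
#' @export
truncate_signal <- function(trace, floor_fraction = 0.25) {
  stopifnot(is.numeric(trace), floor_fraction >= 0)
  pos <- trace[trace > 0]
  if (!length(pos)) {
    stop(paste("truncate_signal: trace has no positive value;",
               "the truncation floor is undefined"), call. = FALSE)
  }
  floor_val <- -floor_fraction * max(pos)
  pmax(trace, floor_val)
}
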