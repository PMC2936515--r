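#' Specify one state of the observing task
#'
#' A state of the semi-Markov trial graph. Time enters only through the state
#' duration; within a trial, events are discrete (0-based event order along
#' the path). Reward is attached to the transition out of a state into the
#' terminal state and may be stochastic (a two-point distribution), which is
#' how the non-discriminative cues deliver the large reward with probability
#' `q` independently of cue identity.
#'
#' @param state_id Symbolic identifier (character scalar).
#' @param duration Seconds spent in the state; must be `>= 0`.
#' @param successors A `data.frame` with columns `state_id` and `prob`, or an
#'   empty list for terminal states. For the choice state the probabilities
#'   are `NA` (the branch is set by the policy); for the trial-start state
#'   they are the trial-type mixture.
#' @param reward_on_exit `NULL` for no reward, or `list(values=, probs=)`
#'   giving the reward distribution on the transition into the terminal
#'   state (in reward units; 1 reward unit = 1 ml of water in the appetitive
#'   task).
#' @param is_choice_state,is_terminal Role flags.
#'
#' @return A `state_spec` list.
#' @export
state_spec <- function(state_id, duration = 0, successors = list(),
                       reward_on_exit = NULL, is_choice_state = FALSE,
                       is_terminal = FALSE) {
  stopifnot(is.character(state_id), length(state_id) == 1L)
  if (!is.numeric(duration) || length(duration) != 1L || is.na(duration) ||
      duration < 0) {
    stop("state '", state_id, "': duration must be a single number >= 0",
         call. = FALSE)
  }
  if (length(successors) && !is.data.frame(successors)) {
    stop("state '", state_id,
         "': successors must be a data.frame(state_id, prob)", call. = FALSE)
  }
  structure(
    list(state_id = state_id, duration = duration, successors = successors,
         reward_on_exit = reward_on_exit,
         is_choice_state = isTRUE(is_choice_state),
         is_terminal = isTRUE(is_terminal)),
    class = "state_spec"
  )
}

.trial_type_labels <- c("forced_informative", "forced_random", "free_choice")

#' Build the observing task graph
#'
#' Constructs the three-trial-type observing task: on every trial the subject
#' passes through a trial-start (fixation) state, then either a forced target
#' (discriminative or non-discriminative) or a choice state from which it
#' selects one of the two targets, then a cue, and finally reward delivery.
#' The discriminative (informative) cues deterministically predict which of
#' the two rewards will arrive; the non-discriminative (random) cues deliver
#' the large reward with probability `q` regardless of cue identity, so they
#' carry no information about the outcome. Expected reward is therefore
#' `q*r_large + (1-q)*r_small` from every pre-cue state, and observing the
#' discriminative cues confers no instrumental advantage.
#'
#' The `delayed` variant models a task in which the choice is between
#' immediate and delayed information: the "delayed" option presents a single
#' non-informative hold state for the cue period, with the discriminative
#' stimulus revealed only at reward time (so it cannot support prediction
#' during the delay).
#'
#' An aversive task is obtained by passing negative reward values (e.g.
#' `r_large = -1`, `r_small = -0.04`); `variant_tag` is then `"aversive"`.
#'
#' @param q Probability of the large reward, in `[0, 1]`.
#' @param r_large,r_small Reward magnitudes in reward units (defaults 1 and
#'   0.04, the 1 ml vs 0.04 ml water volumes of the appetitive task).
#' @param durations Optional named numeric vector of state durations in
#'   seconds, overriding the defaults (start/fixation 1 s, targets 1 s, cues
#'   and the hold state 2.25 s, choice moment 0 s).
#' @param variant `"standard"` or `"delayed"`.
#' @param trial_mixture Probabilities of the three trial types, in the order
#'   forced-informative, forced-random, free-choice; must sum to 1. The
#'   default is 1/3 each (480-trial sessions then contain 160 choice trials
#'   in expectation).
#'
#' @return An `observing_task` object.
#' @examples
#' task <- build_observing_task()
#' validate_task(task)           # character(0)
#' state_expectations(task)[["CUE_RAND_A"]]   # 0.52
#' @export
build_observing_task <- function(q = 0.5, r_large = 1, r_small = 0.04,
                                 durations = NULL,
                                 variant = c("standard", "delayed"),
                                 trial_mixture = c(1, 1, 1) / 3) {
  variant <- match.arg(variant)
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q > 1) {
    stop("q: must be a probability in [0, 1]", call. = FALSE)
  }
  if (length(trial_mixture) != 3L || any(trial_mixture < 0) ||
      abs(sum(trial_mixture) - 1) > 1e-12) {
    stop("trial_mixture: must be three non-negative probabilities summing to 1",
         call. = FALSE)
  }
  dur <- c(START = 1, TGT_INFO = 1, TGT_RAND = 1, CHOICE = 0,
           CUE_LARGE = 2.25, CUE_SMALL = 2.25,
           CUE_RAND_A = 2.25, CUE_RAND_B = 2.25, HOLD = 2.25, END = 0)
  if (!is.null(durations)) {
    bad <- setdiff(names(durations), names(dur))
    if (length(bad)) {
      stop("durations: unknown state(s) ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (any(durations < 0)) {
      stop("durations: negative duration for state(s) ",
           paste(names(durations)[durations < 0], collapse = ", "),
           call. = FALSE)
    }
    dur[names(durations)] <- durations
  }
  succ <- function(ids, probs) data.frame(state_id = ids, prob = probs,
                                          stringsAsFactors = FALSE)
  det_rew <- function(r) list(values = r, probs = 1)
  rand_rew <- list(values = c(r_large, r_small), probs = c(q, 1 - q))

  states <- list(
    START = state_spec("START", dur[["START"]],
                       succ(c("TGT_INFO", "TGT_RAND", "CHOICE"),
                            trial_mixture)),
    TGT_INFO = state_spec("TGT_INFO", dur[["TGT_INFO"]],
                          succ(c("CUE_LARGE", "CUE_SMALL"), c(q, 1 - q))),
    TGT_RAND = if (variant == "standard") {
      state_spec("TGT_RAND", dur[["TGT_RAND"]],
                 succ(c("CUE_RAND_A", "CUE_RAND_B"), c(0.5, 0.5)))
    } else {
      state_spec("TGT_RAND", dur[["TGT_RAND"]], succ("HOLD", 1))
    },
    CHOICE = state_spec("CHOICE", dur[["CHOICE"]],
                        succ(c("TGT_INFO", "TGT_RAND"), c(NA_real_, NA_real_)),
                        is_choice_state = TRUE),
    CUE_LARGE = state_spec("CUE_LARGE", dur[["CUE_LARGE"]], succ("END", 1),
                           reward_on_exit = det_rew(r_large)),
    CUE_SMALL = state_spec("CUE_SMALL", dur[["CUE_SMALL"]], succ("END", 1),
                           reward_on_exit = det_rew(r_small))
  )
  if (variant == "standard") {
    states$CUE_RAND_A <- state_spec("CUE_RAND_A", dur[["CUE_RAND_A"]],
                                    succ("END", 1), reward_on_exit = rand_rew)
    states$CUE_RAND_B <- state_spec("CUE_RAND_B", dur[["CUE_RAND_B"]],
                                    succ("END", 1), reward_on_exit = rand_rew)
  } else {
    states$HOLD <- state_spec("HOLD", dur[["HOLD"]], succ("END", 1),
                              reward_on_exit = rand_rew)
  }
  states$END <- state_spec("END", 0, is_terminal = TRUE)

  trial_types <- data.frame(
    label = .trial_type_labels,
    start_state = c("TGT_INFO", "TGT_RAND", "CHOICE"),
    prob = trial_mixture,
    stringsAsFactors = FALSE
  )
  task <- structure(
    list(states = states, trial_types = trial_types,
         q = q, r_large = r_large, r_small = r_small,
         base_variant = variant, reversed = FALSE),
    class = "observing_task"
  )
  viol <- validate_task(task)
  if (length(viol)) {
    stop("invalid task specification:\n  ",
         paste(viol, collapse = "\n  "), call. = FALSE)
  }
  task
}

#' @export
print.observing_task <- function(x, ...) {
  cat("<observing_task> variant:", variant_tag(x),
      "| q =", x$q, "| rewards:", x$r_large, "/", x$r_small, "\n")
  cat("  states:", paste(names(x$states), collapse = ", "), "\n")
  cat("  trial mixture:",
      paste(sprintf("%s=%.3g", x$trial_types$label, x$trial_types$prob),
            collapse = ", "), "\n")
  invisible(x)
}

#' Variant tag of a task
#'
#' One of `"standard"`, `"delayed"`, `"reversed"`, `"aversive"`. A reversed
#' task reports `"reversed"` regardless of its base variant; a task whose
#' rewards are all non-positive (and not reversed) reports `"aversive"`.
#'
#' @param task An `observing_task`.
#' @return Character scalar.
#' @export
variant_tag <- function(task) {
  if (isTRUE(task$reversed)) return("reversed")
  if (task$r_large < 0 && task$r_small <= 0) return("aversive")
  task$base_variant
}

#' Reverse the target-branch contingencies
#'
#' Swaps the successor sets of the two choice-option targets, so the target
#' that previously led to the discriminative cues now leads to the
#' non-discriminative ones and vice versa (the unsignalled cue-color switch
#' of the reversal manipulation). The manipulation acts on the environment
#' only: learned values are never touched, so relearning after a reversal
#' starts from the pre-reversal values. Applying the reversal twice restores
#' the original contingencies.
#'
#' @param task An `observing_task` (standard or delayed).
#' @return The reversed `observing_task`.
#' @export
apply_reversal <- function(task) {
  stopifnot(inherits(task, "observing_task"))
  a <- task$states$TGT_INFO$successors
  task$states$TGT_INFO$successors <- task$states$TGT_RAND$successors
  task$states$TGT_RAND$successors <- a
  task$reversed <- !isTRUE(task$reversed)
  task
}

#' Draw a trial type from the task mixture
#'
#' Uses R's global random number stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param task An `observing_task`.
#' @param n Number of draws.
#' @return A list (or, for `n > 1`, a data.frame) with the trial-type `label`
#'   and its `start_state` (the state entered from the trial-start state).
#' @export
sample_trial_type <- function(task, n = 1) {
  tt <- task$trial_types
  i <- sample.int(3L, n, replace = TRUE, prob = tt$prob)
  if (n == 1L) {
    list(label = tt$label[i], start_state = tt$start_state[i])
  } else {
    tt[i, c("label", "start_state")]
  }
}

#' Validate a task specification
#'
#' Checks all structural invariants of the observing task and returns a
#' character vector of violation descriptions, each naming the state and the
#' rule it breaks. Validation never raises; an empty vector means the task is
#' valid.
#'
#' @param task An `observing_task` (or a structurally similar list).
#' @return `character()` if valid, otherwise one message per violation.
#' @export
validate_task <- function(task) {
  viol <- character(0)
  st <- task$states
  ids <- names(st)
  add <- function(msg) viol <<- c(viol, msg)
  for (s in st) {
    if (!is.numeric(s$duration) || is.na(s$duration) || s$duration < 0) {
      add(sprintf("state '%s': duration must be >= 0", s$state_id))
    }
    ns <- if (is.data.frame(s$successors)) nrow(s$successors) else 0L
    if (s$is_terminal && ns > 0L) {
      add(sprintf("state '%s': terminal states must have no successors",
                  s$state_id))
    }
    if (!s$is_terminal && ns == 0L) {
      add(sprintf("state '%s': non-terminal state has no successors",
                  s$state_id))
    }
    if (ns > 0L) {
      unknown <- setdiff(s$successors$state_id, ids)
      if (length(unknown)) {
        add(sprintf("state '%s': unknown successor(s) %s", s$state_id,
                    paste(unknown, collapse = ", ")))
      }
      if (!s$is_terminal && !s$is_choice_state) {
        p <- s$successors$prob
        if (anyNA(p) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
          add(sprintf(
            "state '%s': successor probabilities must sum to 1", s$state_id))
        }
      }
    }
  }
  n_choice <- sum(vapply(st, function(s) s$is_choice_state, logical(1)))
  if (n_choice != 1L) {
    add(sprintf("task: exactly one choice state required (found %d)",
                n_choice))
  }
  tt <- task$trial_types
  if (is.null(tt) || abs(sum(tt$prob) - 1) > 1e-9 || any(tt$prob < 0)) {
    add("task: trial-type probabilities must be non-negative and sum to 1")
  } else if (anyDuplicated(tt$label) || anyDuplicated(tt$start_state)) {
    add("task: each trial type must have a unique label and start state")
  }
  if (!is.numeric(task$q) || is.na(task$q) || task$q < 0 || task$q > 1) {
    add("task: q must lie in [0, 1]")
  }
  # reachability of a terminal state from every trial-type start state
  if (!length(viol)) {
    term <- ids[vapply(st, function(s) s$is_terminal, logical(1))]
    reach <- function(from) {
      seen <- character(0); frontier <- from
      while (length(frontier)) {
        seen <- union(seen, frontier)
        nxt <- unlist(lapply(st[frontier], function(s) {
          if (is.data.frame(s$successors)) s$successors$state_id else NULL
        }))
        frontier <- setdiff(nxt, seen)
      }
      seen
    }
    for (k in seq_len(nrow(tt))) {
      if (!any(term %in% reach(tt$start_state[k]))) {
        add(sprintf("trial type '%s': no terminal state reachable from '%s'",
                    tt$label[k], tt$start_state[k]))
      }
    }
    # random cues must have identical, cue-independent reward statistics
    rand_tgt <- if (isTRUE(task$reversed)) "TGT_INFO" else "TGT_RAND"
    if (rand_tgt %in% ids && !st[[rand_tgt]]$is_terminal) {
      cues <- st[[rand_tgt]]$successors$state_id
      rews <- lapply(st[cues], function(s) s$reward_on_exit)
      if (length(rews) > 1L &&
          !all(vapply(rews[-1], identical, logical(1), y = rews[[1]]))) {
        add(sprintf(
          "state '%s': non-discriminative cues must share one reward distribution",
          rand_tgt))
      }
    }
  }
  viol
}

#' Exact state-value expectations by path enumeration
#'
#' Computes the true expected future reward of every state by recursively
#' enumerating all downstream paths (no learning, no disengagement). This is
#' the closed-form benchmark against which the TD iterates and the
#' fixed-point solver are compared: with the disengagement hazard switched
#' off, both must recover these expectations.
#'
#' @param task An `observing_task`.
#' @param choice_p Probability of choosing the first option (the
#'   discriminative target at build time) at the choice state; the true
#'   expectations are independent of it in the observing task since both
#'   branches have equal expected reward.
#' @return Named numeric vector of expected future reward per state
#'   (terminal = 0).
#' @export
state_expectations <- function(task, choice_p = 0.5) {
  st <- task$states
  memo <- new.env(parent = emptyenv())
  exp_rew <- function(s) {
    r <- s$reward_on_exit
    if (is.null(r)) 0 else sum(r$values * r$probs)
  }
  ev <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    s <- st[[id]]
    val <- if (s$is_terminal) {
      0
    } else if (s$is_choice_state) {
      kids <- s$successors$state_id
      choice_p * ev(kids[1]) + (1 - choice_p) * ev(kids[2])
    } else {
      sum(s$successors$prob * vapply(s$successors$state_id, ev, numeric(1))) +
        exp_rew(s)
    }
    memo[[id]] <- val
    val
  }
  setNames(vapply(names(st), ev, numeric(1)), names(st))
}

#' Enumerate all trial paths of one trial type
#'
#' Exhaustively expands the trial tree for a trial type, splitting on every
#' stochastic transition and on every reward outcome, and returns one row per
#' (path, reward) with its probability. Path probabilities sum to 1 and
#' `sum(prob * reward)` is the expected reward of the trial type.
#'
#' @param task An `observing_task`.
#' @param trial_type One of `"forced_informative"`, `"forced_random"`,
#'   `"free_choice"`.
#' @param choice_p Probability of the first option at the choice state.
#' @return A `data.frame` with columns `path` (states joined by `->`),
#'   `prob`, and `reward`.
#' @export
enumerate_trial_paths <- function(task, trial_type, choice_p = 0.5) {
  st <- task$states
  tt <- task$trial_types
  start <- tt$start_state[match(trial_type, tt$label)]
  if (is.na(start)) stop("unknown trial type: ", trial_type, call. = FALSE)
  out <- list()
  walk <- function(id, prob, path, reward) {
    s <- st[[id]]
    if (s$is_terminal) {
      out[[length(out) + 1L]] <<- data.frame(
        path = paste(c(path, id), collapse = "->"),
        prob = prob, reward = reward, stringsAsFactors = FALSE)
      return(invisible())
    }
    kids <- s$successors$state_id
    p <- if (s$is_choice_state) c(choice_p, 1 - choice_p) else s$successors$prob
    for (k in seq_along(kids)) {
      if (p[k] == 0) next
      nxt <- kids[k]
      if (st[[nxt]]$is_terminal && !is.null(s$reward_on_exit)) {
        rw <- s$reward_on_exit
        for (j in seq_along(rw$values)) {
          if (rw$probs[j] == 0) next
          walk(nxt, prob * p[k] * rw$probs[j], c(path, id), rw$values[j])
        }
      } else {
        walk(nxt, prob * p[k], c(path, id), reward)
      }
    }
  }
  walk(start, 1, c("START"), 0)
  do.call(rbind, out)
}
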