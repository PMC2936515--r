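#' Parameters of the Pavlovian disengagement mechanism
#'
#' Engagement (e.g. working-memory maintenance of the task state) is lost
#' stochastically at a per-second hazard that depends on the current
#' predicted value. Two hazard families are supported:
#' \describe{
#'   \item{`valence`}{(default) monotone non-increasing in the signed value:
#'     high-value states protect engagement, predictions of punishment
#'     promote disengagement.}
#'   \item{`salience`}{non-increasing in the absolute value, so a prediction
#'     of a large punishment also protects engagement (an even function of
#'     value).}
#' }
#' The two families make opposite predictions for aversive tasks, which is
#' how the model distinguishes them empirically.
#'
#' The hazard form is `rho(v) = min(1, param_a * exp(-x / param_b))` with
#' `x = v` (valence) or `x = |v|` (salience): a two-parameter, per-second
#' hazard that decreases with value, with `param_a` the hazard at `v = 0`
#' (probability per second) and `param_b` the value scale (reward units).
#' Pass a function as `hazard_fn` to substitute any other hazard with the
#' same contract; it receives the (possibly rectified) value and must return
#' a per-second probability.
#'
#' @param hazard_family `"valence"` or `"salience"`.
#' @param param_a Hazard scale: disengagement probability per second at zero
#'   value; must lie in `[0, 1]`.
#' @param param_b Value scale in reward units; must be `> 0`.
#' @param v_disengaged Fixed value of the disengaged state (shared with the
#'   value table; the simulation functions check consistency).
#' @param hazard_fn Optional replacement hazard function of one argument.
#' @return An `engagement_params` object.
#' @export
engagement_params <- function(hazard_family = c("valence", "salience"),
                              param_a = 0.1, param_b = 0.5,
                              v_disengaged = 0, hazard_fn = NULL) {
  hazard_family <- match.arg(hazard_family)
  if (!is.numeric(param_a) || param_a < 0 || param_a > 1) {
    stop("param_a must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(param_b) || param_b <= 0) {
    stop("param_b must be > 0", call. = FALSE)
  }
  if (!is.null(hazard_fn)) stopifnot(is.function(hazard_fn))
  structure(list(hazard_family = hazard_family, param_a = param_a,
                 param_b = param_b, v_disengaged = v_disengaged,
                 hazard_fn = hazard_fn),
            class = "engagement_params")
}

#' @export
print.engagement_params <- function(x, ...) {
  cat("<engagement_params>", x$hazard_family,
      sprintf("| a = %g /s, b = %g, v_disengaged = %g\n",
              x$param_a, x$param_b, x$v_disengaged))
  invisible(x)
}

#' Per-second disengagement hazard
#'
#' Evaluates the hazard at value `v` (vectorized). For the valence family the
#' hazard is monotone non-increasing in the signed value; for the salience
#' family in `|v|`. The result is clipped to `[0, 1]`.
#'
#' @param v Predicted value(s) in reward units.
#' @param params An [engagement_params()] object.
#' @return Disengagement probability per second, in `[0, 1]`.
#' @examples
#' disengage_hazard(0, engagement_params())   # 0.1
#' @export
disengage_hazard <- function(v, params) {
  x <- if (params$hazard_family == "salience") abs(v) else v
  rho <- if (!is.null(params$hazard_fn)) {
    rep_len(params$hazard_fn(x), length(x))
  } else {
    params$param_a * exp(-x / params$param_b)
  }
  pmin(1, pmax(0, rho))
}

#' Probability of disengaging during a state
#'
#' Compounds the per-second hazard over the time spent in a state:
#' `1 - (1 - rho)^tau`, the per-second Bernoulli survival process
#' generalized to real durations. Its complement is the probability of a
#' correct (engaged) update of the state.
#'
#' @param rho Per-second hazard(s) in `[0, 1]`.
#' @param tau State duration(s) in seconds, `>= 0`.
#' @return Probability of disengaging at some point during the state.
#' @examples
#' p_disengage_state(0.1, 2)   # 1 - 0.9^2 = 0.19
#' @export
p_disengage_state <- function(rho, tau) {
  stopifnot(all(rho >= 0 & rho <= 1), all(tau >= 0))
  1 - (1 - rho)^tau
}

#' Sample an engagement outcome for one state
#'
#' Draws whether engagement is lost during state `s` occupied for `tau`
#' seconds, given the current value table. Once lost, engagement remains lost
#' (the system sits in the fixed disengaged state) until reward delivery at
#' the end of the trial; trial initiation always re-engages.
#'
#' @param V A `value_table`.
#' @param s Non-terminal state id.
#' @param tau Time spent in the state, seconds.
#' @param params An [engagement_params()] object.
#' @return A list with `disengaged` (logical) and `state_of_disengagement`
#'   (`s` if disengaged, else `NA`).
#' @export
sample_engagement <- function(V, s, tau, params) {
  .check_state(V, s)
  p <- p_disengage_state(disengage_hazard(V$values[[s]], params), tau)
  dis <- runif(1) < p
  list(disengaged = dis,
       state_of_disengagement = if (dis) s else NA_character_)
}

#' Cumulative disengagement probability along a trial path
#'
#' For a deterministic trajectory of (state, duration) pairs, returns the
#' analytic probability of having disengaged by the end of each path prefix:
#' `1 - prod(1 - p_i)` over the per-state disengagement probabilities
#' `p_i`. No sampling is involved; the result is monotone non-decreasing
#' along the path.
#'
#' @param trial_path A `data.frame` with columns `state_id` and `tau`.
#' @param V A `value_table` supplying the values at state entry.
#' @param params An [engagement_params()] object.
#' @return Numeric vector, one cumulative probability per path prefix.
#' @export
cumulative_disengagement <- function(trial_path, V, params) {
  stopifnot(is.data.frame(trial_path),
            all(c("state_id", "tau") %in% names(trial_path)))
  p <- vapply(seq_len(nrow(trial_path)), function(i) {
    s <- trial_path$state_id[i]
    .check_state(V, s)
    p_disengage_state(disengage_hazard(V$values[[s]], params),
                      trial_path$tau[i])
  }, numeric(1))
  1 - cumprod(1 - p)
}
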