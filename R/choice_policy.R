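#' Parameters of the softmax choice policy
#'
#' Action selection on free-choice trials follows the softmax/Luce rule with
#' inverse temperature `beta`. Two variants are available:
#' \describe{
#'   \item{`softmax_difference`}{`p = 1 / (1 + exp(-beta * (v1 - v2)))`,
#'     which depends only on the difference of values (shift-invariant).}
#'   \item{`softmax_log`}{the same rule applied to log-values, which depends
#'     only on the ratio of values (scale-invariant):
#'     `p = v1^beta / (v1^beta + v2^beta)`.}
#' }
#' The two variants make different predictions for how the observing bias
#' depends on the reward probability `q` as reward schedules thin.
#'
#' @param beta Inverse temperature, `>= 0`; larger values give more
#'   deterministic choice, and the asymptotic observing bias is monotone in
#'   it.
#' @param rule `"softmax_difference"` (default) or `"softmax_log"`.
#' @return A `policy_params` object.
#' @export
policy_params <- function(beta = 10,
                          rule = c("softmax_difference", "softmax_log")) {
  rule <- match.arg(rule)
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0) {
    stop("beta must be a single number >= 0", call. = FALSE)
  }
  structure(list(beta = beta, rule = rule), class = "policy_params")
}

#' @export
print.policy_params <- function(x, ...) {
  cat("<policy_params>", x$rule, "| beta =", x$beta, "\n")
  invisible(x)
}

#' Probability of choosing the informative option
#'
#' Evaluates the softmax choice probability for the discriminative
#' (informative) option given the two option values. Uses the numerically
#' stable logistic, so large `beta * (v_info - v_rand)` saturates cleanly at
#' 0 or 1. For the log rule both values must be strictly positive (during
#' simulation values are clamped at a small positive floor before taking
#' logarithms, since early learning can transiently produce non-positive
#' values; the exported function itself refuses non-positive input).
#'
#' @param v_info,v_rand Values of the informative and random options, reward
#'   units (vectorized).
#' @param params A [policy_params()] object.
#' @return Probability of choosing the informative option, in `[0, 1]`.
#' @examples
#' choice_prob(0.5, 0, policy_params(beta = 2))   # 1/(1 + exp(-1))
#' @export
choice_prob <- function(v_info, v_rand, params) {
  if (params$rule == "softmax_log") {
    if (any(v_info <= 0) || any(v_rand <= 0)) {
      stop("softmax_log requires strictly positive values", call. = FALSE)
    }
    plogis(params$beta * (log(v_info) - log(v_rand)))
  } else {
    plogis(params$beta * (v_info - v_rand))
  }
}

#' Sample a choice
#'
#' Bernoulli draw of the chosen option from the probability of the
#' informative option, using R's global random number stream.
#'
#' @param p Probability of the informative option, in `[0, 1]`.
#' @return `"informative"` or `"random"`.
#' @export
sample_choice <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  if (runif(1) < p) "informative" else "random"
}
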