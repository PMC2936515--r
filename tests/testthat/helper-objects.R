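# Shared fixtures, built in code.

default_task <- function(...) build_observing_task(...)

# engagement with the hazard switched off (the no-mechanism control)
eng_off <- function(v_disengaged = 0) {
  engagement_params(param_a = 0, v_disengaged = v_disengaged)
}

# run the internal engine on a task and return its raw result
engine_run <- function(task, n, alpha = 0.1, eng = engagement_params(),
                       pol = policy_params(), v0 = 0, v_d = eng$v_disengaged,
                       seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ct <- observeTD:::.compile_task(task)
  V <- rep(v0, ct$n)
  V[ct$is_term] <- 0
  res <- observeTD:::.sim_engine(ct, V, v_d, alpha, eng, pol, as.integer(n),
                                 ...)
  res$ct <- ct
  res
}

engine_events <- function(res) observeTD:::.events_df(res$ct, res)

pooled_bias <- function(sessions) {
  sum(sessions$n_info) / sum(sessions$n_choice)
}
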