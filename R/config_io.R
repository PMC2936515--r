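# Reading and writing task / experiment configurations as YAML or JSON, and
# tabular outputs of simulation runs.

.task_to_list <- function(task) {
  list(
    states = lapply(unname(task$states), function(s) {
      out <- list(state_id = s$state_id, duration = s$duration)
      if (is.data.frame(s$successors) && nrow(s$successors)) {
        out$successors <- lapply(seq_len(nrow(s$successors)), function(i) {
          k <- list(state_id = s$successors$state_id[i])
          # policy-resolved branches (the choice state) carry no probability
          if (!is.na(s$successors$prob[i])) k$prob <- s$successors$prob[i]
          k
        })
      }
      if (!is.null(s$reward_on_exit)) out$reward_on_exit <- s$reward_on_exit
      if (s$is_choice_state) out$is_choice_state <- TRUE
      if (s$is_terminal) out$is_terminal <- TRUE
      out
    }),
    trial_types = lapply(seq_len(nrow(task$trial_types)), function(i) {
      as.list(task$trial_types[i, ])
    }),
    q = task$q, r_large = task$r_large, r_small = task$r_small,
    variant_tag = variant_tag(task),
    base_variant = task$base_variant, reversed = isTRUE(task$reversed)
  )
}

.task_from_list <- function(x) {
  req <- c("states", "trial_types", "q", "r_large", "r_small")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    stop("task config: missing key(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  states <- list()
  for (s in x$states) {
    succ <- if (is.null(s$successors)) list() else {
      data.frame(
        state_id = vapply(s$successors, `[[`, character(1), "state_id"),
        prob = vapply(s$successors, function(k) {
          p <- k$prob
          if (is.null(p)) NA_real_ else as.numeric(p)
        }, numeric(1)),
        stringsAsFactors = FALSE)
    }
    rew <- if (is.null(s$reward_on_exit)) NULL else {
      list(values = as.numeric(unlist(s$reward_on_exit$values)),
           probs = as.numeric(unlist(s$reward_on_exit$probs)))
    }
    states[[s$state_id]] <- state_spec(
      s$state_id, as.numeric(s$duration), succ, rew,
      is_choice_state = isTRUE(s$is_choice_state),
      is_terminal = isTRUE(s$is_terminal))
  }
  tt <- do.call(rbind, lapply(x$trial_types, function(k) {
    data.frame(label = k$label, start_state = k$start_state,
               prob = as.numeric(k$prob), stringsAsFactors = FALSE)
  }))
  structure(
    list(states = states, trial_types = tt, q = as.numeric(x$q),
         r_large = as.numeric(x$r_large), r_small = as.numeric(x$r_small),
         base_variant = if (is.null(x$base_variant)) "standard"
           else x$base_variant,
         reversed = isTRUE(x$reversed)),
    class = "observing_task")
}

.fmt_of <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) "yaml"
  else if (ext == "json") "json"
  else stop("config files must end in .yaml/.yml or .json", call. = FALSE)
}

#' Write a model configuration to YAML or JSON
#'
#' Serializes the task (and optionally the engagement and policy parameters)
#' to a single document. The format is chosen from the file extension.
#'
#' @param task An `observing_task`.
#' @param path Output path ending in `.yaml`, `.yml`, or `.json`.
#' @param eng,policy Optional [engagement_params()] / [policy_params()] to
#'   embed under keys `engagement` and `policy`.
#' @return `path`, invisibly.
#' @export
write_config <- function(task, path, eng = NULL, policy = NULL) {
  doc <- list(task = .task_to_list(task))
  if (!is.null(eng)) {
    doc$engagement <- list(hazard_family = eng$hazard_family,
                           param_a = eng$param_a, param_b = eng$param_b,
                           v_disengaged = eng$v_disengaged)
  }
  if (!is.null(policy)) {
    doc$policy <- list(beta = policy$beta, rule = policy$rule)
  }
  if (.fmt_of(path) == "yaml") {
    yaml::write_yaml(doc, path, precision = 15)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a model configuration from YAML or JSON
#'
#' Parses a document written by [write_config()] (or hand-written to the
#' same schema), validates the task, and rebuilds the parameter objects.
#' Invalid tasks raise an error listing every violation.
#'
#' @param path Config path ending in `.yaml`, `.yml`, or `.json`.
#' @return A list with `task` and, when present in the document,
#'   `engagement` and `policy`.
#' @export
read_config <- function(path) {
  doc <- if (.fmt_of(path) == "yaml") {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  if (is.null(doc$task)) stop("config: missing 'task' key", call. = FALSE)
  task <- .task_from_list(doc$task)
  viol <- validate_task(task)
  if (length(viol)) {
    stop("config: invalid task:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  }
  out <- list(task = task)
  if (!is.null(doc$engagement)) {
    e <- doc$engagement
    out$engagement <- engagement_params(
      hazard_family = e$hazard_family, param_a = e$param_a,
      param_b = e$param_b,
      v_disengaged = if (is.null(e$v_disengaged)) 0 else e$v_disengaged)
  }
  if (!is.null(doc$policy)) {
    out$policy <- policy_params(beta = doc$policy$beta,
                                rule = doc$policy$rule)
  }
  out
}

#' Write the tabular outputs of a run
#'
#' Writes `sessions.csv` (session, n_choice, n_info, bias, ci_low, ci_high),
#' and when present in the run, `trials.csv` and `td_events.csv` (columns
#' trial, event, state, delta, engaged, in deterministic trial-then-event
#' order), plus a `run_manifest.json` recording the configuration hash, the
#' master seed, and the package version.
#'
#' @param run An `observing_run` (from [run_acquisition()] or
#'   [run_reversal()]).
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  stopifnot(inherits(run, "observing_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(run$sessions, file.path(dir, "sessions.csv"), row.names = FALSE)
  if (!is.null(run$trials)) {
    write.csv(run$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  }
  if (!is.null(run$events)) {
    write.csv(run$events, file.path(dir, "td_events.csv"),
              row.names = FALSE)
  }
  cfg <- tempfile(fileext = ".json")
  on.exit(unlink(cfg))
  write_config(run$task, cfg, eng = run$eng, policy = run$policy)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg)),
    seed = run$seed,
    alpha = run$alpha,
    n_trials_per_session = run$n_trials,
    package = "observeTD",
    version = as.character(packageVersion("observeTD"))
  )
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
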