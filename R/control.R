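# Process control: drive the executing model (BPMN, CMMN or a combination)
# from recognized situations.
#
# Convention: an observation marks the *start* of a situation.  The
# controller tracks one current situation; recognizing a new step completes
# the previously running task ("the matching running task is completed, so
# that the next possible tasks are activated"), performs whatever
# housekeeping the notation demands (manual start of optional items, manual
# stage completion, case complete/close and call-activity hops), and makes
# the recognized step the new current situation.  All of this is applied
# transactionally: a refused observation leaves the runtime untouched.

control_action <- function(kind, element = NA_character_, reason = "") {
  structure(list(kind = kind, element = element, reason = reason),
            class = "control_action")
}

ctl_ok <- function(runtime, actions) {
  list(ok = TRUE, runtime = runtime, actions = actions, reason = "")
}
ctl_fail <- function(reason) {
  list(ok = FALSE, runtime = NULL, actions = list(), reason = reason)
}

refusal_reason <- function(e) {
  if (inherits(e, "surgflow_regression")) "regression"
  else if (inherits(e, "surgflow_bypassed_task")) "delayed-optional"
  else if (inherits(e, "surgflow_out_of_order")) "out-of-order"
  else if (inherits(e, "surgflow_lifecycle_error")) "lifecycle"
  else if (inherits(e, "surgflow_stage_incomplete")) "stage-incomplete"
  else if (inherits(e, "surgflow_case_incomplete")) "case-incomplete"
  else conditionMessage(e)
}

#' Compute and apply the control actions for a recognized situation
#'
#' Dispatches on the runtime kind.  On success the returned runtime has the
#' previous situation completed and the candidate activated; on refusal the
#' runtime is unchanged and the reason is reported.
#'
#' @param runtime A `process_instance`, `case_instance` or
#'   `combination_instance`.
#' @param candidate The recognized step id.
#' @param current The previously running step id, or `NA`.
#' @return A list with `ok`, `runtime`, `actions` (list of control actions)
#'   and `reason`.
#' @export
step_controller <- function(runtime, candidate, current = NA_character_) {
  if (!is.na(current) && identical(candidate, current)) {
    return(ctl_ok(runtime, list(control_action("none", candidate, "repetition"))))
  }
  UseMethod("step_controller")
}

#' @export
step_controller.process_instance <- function(runtime, candidate,
                                             current = NA_character_) {
  actions <- list()
  rt <- runtime
  if (!is.na(current)) {
    res <- tryCatch(
      list(rt = complete_task(rt, current)),
      surgflow_error = function(e) e
    )
    if (inherits(res, "condition")) return(ctl_fail(refusal_reason(res)))
    rt <- res$rt
    actions <- c(actions, list(control_action("complete_task", current)))
  }
  if (candidate %in% active_tasks(rt)) return(ctl_ok(rt, actions))
  # classify the refusal against the *original* runtime
  st <- tryCatch(task_states(runtime)[[candidate]], error = function(e) NULL)
  if (is.null(st) || is.na(st)) return(ctl_fail("unknown-step"))
  ctl_fail(switch(st,
    completed = "regression",
    bypassed = "delayed-optional",
    "out-of-order"))
}

# advance within a case instance until the candidate is active; may complete
# stages whose requirements are met
cmmn_reach_candidate <- function(rt, candidate, actions, max_hops = 25L) {
  for (hop in seq_len(max_hops)) {
    st <- tryCatch(item_state(rt, candidate), surgflow_error = function(e) NULL)
    if (is.null(st)) return(ctl_fail("unknown-step"))
    if (st == "active") return(ctl_ok(rt, actions))
    if (st == "enabled") {
      rt <- manually_start(rt, candidate)
      actions <- c(actions, list(control_action("manual_start", candidate)))
      return(ctl_ok(rt, actions))
    }
    if (st == "completed") return(ctl_fail("regression"))
    if (st == "disabled") return(ctl_fail("disabled-optional"))
    # available: try to complete one finished stage so its sentries fire
    progressed <- FALSE
    for (id in names(rt$index)) {
      it <- rt$index[[id]]$item
      if (it$kind != "stage" || item_state(rt, id) != "active") next
      rt2 <- tryCatch(complete_stage(rt, id), surgflow_error = function(e) NULL)
      if (is.null(rt2)) next
      rt <- rt2
      actions <- c(actions, list(control_action("complete_stage", id)))
      progressed <- TRUE
      break
    }
    if (!progressed) return(ctl_fail("out-of-order"))
  }
  ctl_fail("out-of-order")
}

#' @export
step_controller.case_instance <- function(runtime, candidate,
                                          current = NA_character_) {
  actions <- list()
  rt <- runtime
  if (!is.na(current) && item_state(rt, current) == "active") {
    res <- tryCatch(list(rt = complete_task(rt, current)),
                    surgflow_error = function(e) e)
    if (inherits(res, "condition")) return(ctl_fail(refusal_reason(res)))
    rt <- res$rt
    actions <- c(actions, list(control_action("complete_task", current)))
  }
  cmmn_reach_candidate(rt, candidate, actions)
}

# Combination runtime --------------------------------------------------------

#' Start a combination-model runtime
#'
#' The root process starts immediately; referenced cases are started lazily
#' when the controller enters their call activity.
#'
#' @param model A [combination_model()].
#' @param camunda_compat Engine-compatibility flag for the root process.
#' @return A `combination_instance`.
#' @export
start_combination <- function(model, camunda_compat = TRUE) {
  validate_combination_model(model)
  case_of_task <- character(0)
  for (cs in model$cases) {
    for (t in case_task_ids(cs)) case_of_task[t] <- cs$case_id
  }
  call_of_case <- character(0)
  for (n in all_nodes_flat(model$root)) {
    if (n$kind == "call_activity") call_of_case[n$called_case] <- n$node_id
  }
  structure(
    list(
      model = model,
      root = start_process(model$root, camunda_compat = camunda_compat),
      cases = list(), active_case = NA_character_,
      case_of_task = case_of_task, call_of_case = call_of_case
    ),
    class = "combination_instance"
  )
}

comb_location <- function(rt, step_id) {
  if (step_id %in% names(rt$case_of_task)) rt$case_of_task[[step_id]]
  else if (blk_contains(rt$root$tree, step_id)) "root"
  else NA_character_
}

# complete remaining stages, complete + close the active case, and complete
# its call activity in the root process
comb_settle_active_case <- function(rt, actions) {
  cid <- rt$active_case
  ci <- rt$cases[[cid]]
  res <- tryCatch({
    for (hop in seq_len(25L)) {
      stages <- names(ci$index)[vapply(ci$index, function(e)
        e$item$kind == "stage", logical(1))]
      stages <- stages[vapply(stages, function(s)
        item_state(ci, s) == "active", logical(1))]
      done_one <- FALSE
      for (s in stages) {
        ci2 <- tryCatch(complete_stage(ci, s), surgflow_error = function(e) NULL)
        if (!is.null(ci2)) {
          ci <- ci2
          actions <- c(actions, list(control_action("complete_stage", s)))
          done_one <- TRUE
          break
        }
      }
      if (!done_one) break
    }
    ci <- complete_case(ci)
    actions <- c(actions, list(control_action("complete_case", cid)))
    ci <- close_case(ci)
    actions <- c(actions, list(control_action("close_case", cid)))
    list(ci = ci, actions = actions)
  }, surgflow_error = function(e) e)
  if (inherits(res, "condition")) return(ctl_fail(refusal_reason(res)))
  rt$cases[[cid]] <- res$ci
  root2 <- tryCatch(complete_task(rt$root, rt$call_of_case[[cid]]),
                    surgflow_error = function(e) e)
  if (inherits(root2, "condition")) return(ctl_fail(refusal_reason(root2)))
  rt$root <- root2
  rt$active_case <- NA_character_
  ctl_ok(rt, res$actions)
}

comb_enter_case <- function(rt, cid, actions) {
  ca <- rt$call_of_case[[cid]]
  if (!ca %in% active_tasks(rt$root)) return(ctl_fail("out-of-order"))
  rt$cases[[cid]] <- start_case(rt$model$cases[[cid]])
  rt$active_case <- cid
  actions <- c(actions, list(control_action("enter_call_activity", ca)))
  ctl_ok(rt, actions)
}

#' @export
step_controller.combination_instance <- function(runtime, candidate,
                                                 current = NA_character_) {
  rt <- runtime
  actions <- list()
  cand_loc <- comb_location(rt, candidate)
  if (is.na(cand_loc)) return(ctl_fail("unknown-step"))
  cur_loc <- if (is.na(current)) NA_character_ else comb_location(rt, current)

  # 1. complete the running situation where it lives
  if (!is.na(current)) {
    if (identical(cur_loc, "root")) {
      res <- tryCatch(list(rt = complete_task(rt$root, current)),
                      surgflow_error = function(e) e)
      if (inherits(res, "condition")) return(ctl_fail(refusal_reason(res)))
      rt$root <- res$rt
    } else {
      ci <- rt$cases[[cur_loc]]
      if (!is.null(ci) && item_state(ci, current) == "active") {
        ci2 <- tryCatch(complete_task(ci, current), surgflow_error = function(e) e)
        if (inherits(ci2, "condition")) return(ctl_fail(refusal_reason(ci2)))
        rt$cases[[cur_loc]] <- ci2
      }
    }
    actions <- c(actions, list(control_action("complete_task", current)))
  }

  # 2. hop containers until the candidate's location is active
  if (identical(cand_loc, "root")) {
    if (!is.na(rt$active_case)) {
      res <- comb_settle_active_case(rt, actions)
      if (!res$ok) return(res)
      rt <- res$runtime; actions <- res$actions
    }
    if (candidate %in% active_tasks(rt$root)) return(ctl_ok(rt, actions))
    return(ctl_fail("out-of-order"))
  }
  if (!identical(rt$active_case, cand_loc)) {
    if (!is.na(rt$active_case)) {
      res <- comb_settle_active_case(rt, actions)
      if (!res$ok) return(res)
      rt <- res$runtime; actions <- res$actions
    }
    res <- comb_enter_case(rt, cand_loc, actions)
    if (!res$ok) return(res)
    rt <- res$runtime; actions <- res$actions
  }
  ci <- rt$cases[[cand_loc]]
  res <- cmmn_reach_candidate(ci, candidate, actions)
  if (!res$ok) return(res)
  rt$cases[[cand_loc]] <- res$runtime
  ctl_ok(rt, res$actions)
}

# Finalization at end of stream ----------------------------------------------

finalize_runtime <- function(runtime, current) UseMethod("finalize_runtime")

#' @export
finalize_runtime.process_instance <- function(runtime, current) {
  actions <- list()
  if (!is.na(current)) {
    rt <- tryCatch(complete_task(runtime, current), surgflow_error = function(e) NULL)
    if (!is.null(rt)) {
      runtime <- rt
      actions <- list(control_action("complete_task", current))
    }
  }
  list(runtime = runtime, actions = actions, completed = is_complete(runtime))
}

#' @export
finalize_runtime.case_instance <- function(runtime, current) {
  actions <- list()
  ci <- runtime
  if (!is.na(current) && item_state(ci, current) == "active") {
    ci2 <- tryCatch(complete_task(ci, current), surgflow_error = function(e) NULL)
    if (!is.null(ci2)) {
      ci <- ci2
      actions <- c(actions, list(control_action("complete_task", current)))
    }
  }
  settled <- tryCatch({
    for (hop in seq_len(25L)) {
      stages <- names(ci$index)[vapply(ci$index, function(e)
        e$item$kind == "stage" && item_state(ci, e$item$item_id) == "active",
        logical(1))]
      done_one <- FALSE
      for (s in stages) {
        ci2 <- tryCatch(complete_stage(ci, s), surgflow_error = function(e) NULL)
        if (!is.null(ci2)) {
          ci <- ci2
          actions <- c(actions, list(control_action("complete_stage", s)))
          done_one <- TRUE
          break
        }
      }
      if (!done_one) break
    }
    ci <- complete_case(ci)
    actions <- c(actions, list(control_action("complete_case", ci$case$case_id)))
    ci <- close_case(ci)
    actions <- c(actions, list(control_action("close_case", ci$case$case_id)))
    TRUE
  }, surgflow_error = function(e) FALSE)
  list(runtime = ci, actions = actions,
       completed = settled && ci$case_state == "closed")
}

#' @export
finalize_runtime.combination_instance <- function(runtime, current) {
  rt <- runtime
  actions <- list()
  if (!is.na(current)) {
    loc <- comb_location(rt, current)
    if (identical(loc, "root")) {
      r2 <- tryCatch(complete_task(rt$root, current), surgflow_error = function(e) NULL)
      if (!is.null(r2)) {
        rt$root <- r2
        actions <- c(actions, list(control_action("complete_task", current)))
      }
    } else if (!is.na(loc) && !is.null(rt$cases[[loc]])) {
      ci2 <- tryCatch(complete_task(rt$cases[[loc]], current),
                      surgflow_error = function(e) NULL)
      if (!is.null(ci2)) {
        rt$cases[[loc]] <- ci2
        actions <- c(actions, list(control_action("complete_task", current)))
      }
    }
  }
  if (!is.na(rt$active_case)) {
    res <- comb_settle_active_case(rt, actions)
    if (res$ok) {
      rt <- res$runtime
      actions <- res$actions
    }
  }
  all_closed <- all(vapply(rt$cases, function(c) c$case_state == "closed",
                           logical(1)))
  list(runtime = rt, actions = actions,
       completed = is_complete(rt$root) && all_closed &&
         length(rt$cases) > 0)
}

# Session loop ----------------------------------------------------------------

#' Run a recognition-and-control session
#'
#' Iterates recognize -> control over an observation stream, driving the
#' chosen deployed variant of the intervention model.  Process knowledge is
#' always derived from the BPMN variant of the bundle.  The report holds one
#' row per observation (recognition result, actions, refusals) plus the final
#' completion status and duration estimates; refused observations never
#' change the runtime state.
#'
#' @param bundle A model bundle from [build_models()] (or a list with
#'   elements `bpmn`, `cmmn`, `structured`, `mixed`, `rules`).
#' @param stream List of [sensor_observation()] objects.
#' @param rules List of [situation_rule()] objects; defaults to the bundle's.
#' @param config A [session_config()].
#' @param variant Which deployed model to control.
#' @return A `session_report`: data frame `rows`, final `completed` flag,
#'   `refusals` count, the completed-step `trace`, the `actions` list and the
#'   final `runtime`.
#' @export
run_session <- function(bundle, stream, rules = NULL,
                        config = session_config(),
                        variant = c("bpmn", "cmmn", "structured", "mixed")) {
  variant <- match.arg(variant)
  rules <- rules %||% bundle$rules
  kmodel <- bundle$bpmn
  impact <- impact_config(config$sensor_weight)
  runtime <- switch(variant,
    bpmn = start_process(bundle$bpmn, camunda_compat = config$camunda_compat),
    cmmn = start_case(bundle$cmmn),
    structured = start_combination(bundle$structured, config$camunda_compat),
    mixed = start_combination(bundle$mixed, config$camunda_compat)
  )
  first_phase_steps <- first_phase_step_ids(kmodel)
  current <- NA_character_
  trace <- character(0)
  step_ids <- model_task_ids(kmodel)
  rows <- list()
  all_actions <- list()

  for (i in seq_along(stream)) {
    obs <- stream[[i]]
    sk <- recognize(obs, kmodel, trace, rules, impact,
                    current = if (is.na(current)) NULL else current,
                    camunda_compat = config$camunda_compat)
    reasonable <- sk$reasonable
    if (variant != "bpmn" && config$first_stage_exception &&
        !is.na(sk$best) && sk$best %in% first_phase_steps) {
      # plausibility checking does not veto first-stage candidates
      reasonable <- TRUE
    }
    if (is.na(sk$best)) {
      rows[[i]] <- session_row(i, obs, sk, accepted = FALSE,
                               actions = list(control_action("none", reason = "no-evidence")),
                               reason = "no-evidence", trace, obs$time, kmodel,
                               config)
      next
    }
    res <- step_controller(runtime, sk$best, current)
    if (res$ok) {
      runtime <- res$runtime
      done_steps <- vapply(
        Filter(function(a) a$kind == "complete_task", res$actions),
        `[[`, character(1), "element")
      trace <- c(trace, intersect(done_steps, step_ids))
      if (!identical(sk$best, current)) current <- sk$best
      all_actions <- c(all_actions, res$actions)
      rows[[i]] <- session_row(i, obs, sk, accepted = TRUE, actions = res$actions,
                               reason = "", trace, obs$time, kmodel, config,
                               reasonable = reasonable)
    } else {
      rows[[i]] <- session_row(i, obs, sk, accepted = FALSE,
                               actions = list(control_action("none", sk$best, res$reason)),
                               reason = res$reason, trace, obs$time, kmodel,
                               config, reasonable = reasonable)
    }
  }

  fin <- finalize_runtime(runtime, current)
  runtime <- fin$runtime
  done_steps <- vapply(
    Filter(function(a) a$kind == "complete_task", fin$actions),
    `[[`, character(1), "element")
  trace <- c(trace, intersect(done_steps, step_ids))
  all_actions <- c(all_actions, fin$actions)

  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  refusals <- sum(!df$accepted & df$reason != "repetition")
  structure(
    list(rows = df, completed = fin$completed, refusals = refusals,
         trace = trace, actions = all_actions, runtime = runtime,
         variant = variant, config = config),
    class = "session_report"
  )
}

first_phase_step_ids <- function(model) {
  for (n in model$nodes) {
    if (n$kind == "sub_process")
      return(vapply(n$children[vapply(n$children, `[[`, character(1), "kind") == "user_task"],
                    `[[`, character(1), "node_id"))
  }
  character(0)
}

session_row <- function(i, obs, sk, accepted, actions, reason, trace, clock,
                        kmodel, config, reasonable = sk$reasonable) {
  est <- remaining_duration(kmodel, trace, clock, config$camunda_compat)
  data.frame(
    obs = i, time = obs$time,
    recognized = if (is.na(sk$best)) NA_character_ else sk$best,
    probability = sk$best_probability,
    reasonable = isTRUE(reasonable),
    accepted = accepted,
    actions = paste(vapply(actions, function(a)
      if (nzchar(a$reason)) sprintf("%s(%s:%s)", a$kind, a$element, a$reason)
      else sprintf("%s(%s)", a$kind, a$element), character(1)), collapse = "; "),
    reason = reason,
    rsd = est$rsd, delay = est$delay,
    stringsAsFactors = FALSE
  )
}

#' Write a session report as line-delimited JSON records
#'
#' @param report A `session_report`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_session_report <- function(report, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(report$rows))) {
    writeLines(jsonlite::toJSON(as.list(report$rows[i, ]), auto_unbox = TRUE,
                                na = "null"), con)
  }
  writeLines(jsonlite::toJSON(list(
    summary = TRUE, completed = report$completed, refusals = report$refusals,
    trace = report$trace, variant = report$variant
  ), auto_unbox = TRUE), con)
  invisible(path)
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report> variant=%s, %d observations\n",
              x$variant, nrow(x$rows)))
  cat(sprintf("  completed: %s, refusals: %d\n", x$completed, x$refusals))
  cat(sprintf("  trace (%d steps): %s\n", length(x$trace),
              paste(x$trace, collapse = " > ")))
  invisible(x)
}
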