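# Plan-item lifecycle engine for the supported CMMN subset.
#
# Lifecycle states: available -> enabled (manual activation) -> active ->
# completed, with optional items movable to disabled when their stage closes.
# Sentries are completion dependencies: an entry criterion is satisfied once
# every referenced item has completed.  Stages activate automatically when
# their criteria fire; a stage containing optional items must be completed
# explicitly, mirroring the engine behavior this package reproduces.

index_case_items <- function(case) {
  out <- list()
  walk <- function(items, parent) {
    for (it in items) {
      out[[it$item_id]] <<- list(item = it, parent = parent)
      if (length(it$children)) walk(it$children, it$item_id)
    }
  }
  walk(case$plan_items, NA_character_)
  out
}

#' Start a case instance
#'
#' All plan items begin `available`; items whose entry criteria are satisfied
#' (trivially so when they have none) and whose parent stage is active become
#' `active` (required, automatic activation) or `enabled` (manual
#' activation).  Stages activate automatically.
#'
#' @param case A [case_model()].
#' @return A `case_instance`.
#' @export
start_case <- function(case) {
  validate_case_model(case)
  idx <- index_case_items(case)
  inst <- structure(
    list(
      case = case, index = idx,
      item_states = stats::setNames(rep("available", length(idx)), names(idx)),
      case_state = "active", trace = character(0), log = list()
    ),
    class = "case_instance"
  )
  evaluate_case(inst)
}

item_state <- function(inst, id) {
  s <- inst$item_states[id]
  if (is.na(s)) sf_lookup_error(id, "plan item")
  unname(s)
}

parent_active <- function(inst, id) {
  p <- inst$index[[id]]$parent
  if (is.na(p)) inst$case_state == "active" else item_state(inst, p) == "active"
}

criteria_satisfied <- function(inst, id) {
  crit <- inst$index[[id]]$item$entry_criteria
  if (!length(crit)) return(TRUE)
  any(vapply(crit, function(s) {
    all(vapply(s$on_parts, function(op)
      item_state(inst, op$source) == "completed", logical(1)))
  }, logical(1)))
}

stage_children <- function(inst, id) names(inst$index[[id]]$item$children)

stage_has_optional_children <- function(inst, id) {
  any(!vapply(inst$index[[id]]$item$children, `[[`, logical(1), "required"))
}

# fixpoint: fire sentries, activate items, auto-complete all-required stages
evaluate_case <- function(inst) {
  repeat {
    changed <- FALSE
    for (id in names(inst$index)) {
      it <- inst$index[[id]]$item
      st <- item_state(inst, id)
      if (st == "available" && parent_active(inst, id) &&
          criteria_satisfied(inst, id)) {
        if (it$kind == "stage") {
          inst$item_states[id] <- "active"; changed <- TRUE
        } else if (it$kind == "human_task") {
          inst$item_states[id] <-
            if (it$manual_activation) "enabled" else "active"
          changed <- TRUE
        }
        # event listeners stay available: no runtime semantics
      }
      if (it$kind == "stage" && item_state(inst, id) == "active" &&
          !stage_has_optional_children(inst, id)) {
        kid_states <- inst$item_states[stage_children(inst, id)]
        kid_kinds <- vapply(inst$index[[id]]$item$children, `[[`,
                            character(1), "kind")
        relevant <- kid_kinds != "event_listener"
        if (length(kid_states[relevant]) &&
            all(kid_states[relevant] == "completed")) {
          inst$item_states[id] <- "completed"; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  inst
}

assert_mutable <- function(inst) {
  if (inst$case_state == "closed") sf_immutable_case(inst$case$case_id)
  invisible(TRUE)
}

#' Manually start an enabled plan item
#'
#' Optional items (manual activation rule) wait in state `enabled` once their
#' entry criteria fire; this transition moves them to `active`.
#'
#' @param instance A `case_instance`.
#' @param item_id Plan-item id.
#' @return The updated `case_instance`.
#' @export
manually_start <- function(instance, item_id) {
  assert_mutable(instance)
  st <- item_state(instance, item_id)
  if (st != "enabled") sf_lifecycle_error(item_id, st, "enabled")
  instance$item_states[item_id] <- "active"
  instance$log <- c(instance$log, list(log_record(
    instance$case$case_id, item_id, "manual_start", NA_real_)))
  instance
}

#' @export
complete_task.case_instance <- function(instance, task_id, clock = NULL) {
  assert_mutable(instance)
  st <- item_state(instance, task_id)
  it <- instance$index[[task_id]]$item
  if (it$kind != "human_task")
    sf_lifecycle_error(task_id, st, "active human task")
  if (st != "active") sf_lifecycle_error(task_id, st, "active")
  instance$item_states[task_id] <- "completed"
  instance$trace <- c(instance$trace, task_id)
  instance$log <- c(instance$log, list(log_record(
    instance$case$case_id, task_id, "complete", clock %||% NA_real_)))
  evaluate_case(instance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Complete a stage
#'
#' Requires every required child completed and no child active.  Remaining
#' enabled or available optional children are disabled.  Stages without
#' optional children complete automatically when their last required child
#' completes; calling this on an already completed stage is a no-op.
#'
#' @param instance A `case_instance`.
#' @param stage_id Plan-item id of the stage.
#' @return The updated `case_instance`.
#' @export
complete_stage <- function(instance, stage_id) {
  assert_mutable(instance)
  it <- instance$index[[stage_id]]$item
  if (is.null(it) || it$kind != "stage") sf_lookup_error(stage_id, "stage")
  st <- item_state(instance, stage_id)
  if (st == "completed") return(instance)  # auto-completed already
  if (st != "active") sf_lifecycle_error(stage_id, st, "active")
  kids <- stage_children(instance, stage_id)
  req <- kids[vapply(instance$index[[stage_id]]$item$children, function(k)
    k$required && k$kind != "event_listener", logical(1))]
  missing <- req[instance$item_states[req] != "completed"]
  if (length(missing)) sf_stage_incomplete(stage_id, missing)
  act <- kids[instance$item_states[kids] == "active"]
  if (length(act)) sf_stage_busy(stage_id, act)
  opt <- kids[instance$item_states[kids] %in% c("enabled", "available")]
  instance$item_states[opt] <- "disabled"
  instance$item_states[stage_id] <- "completed"
  instance$log <- c(instance$log, list(log_record(
    instance$case$case_id, stage_id, "complete_stage", NA_real_)))
  evaluate_case(instance)
}

#' Complete and close a case
#'
#' The case never completes automatically: after the last task the system must
#' complete and then close it.  Completion requires every required plan item
#' completed and no item active; remaining optional items are disabled.
#' A closed case is immutable.
#'
#' @param instance A `case_instance`.
#' @return The updated `case_instance`.
#' @export
complete_case <- function(instance) {
  assert_mutable(instance)
  ids <- names(instance$index)
  req <- ids[vapply(instance$index, function(e)
    e$item$required && e$item$kind != "event_listener", logical(1))]
  missing <- req[instance$item_states[req] != "completed"]
  if (length(missing)) sf_case_incomplete(instance$case$case_id, missing)
  act <- ids[instance$item_states[ids] == "active"]
  act <- act[vapply(act, function(i)
    instance$index[[i]]$item$kind == "human_task", logical(1))]
  if (length(act)) sf_stage_busy(instance$case$case_id, act)
  opt <- ids[instance$item_states[ids] %in% c("enabled", "available")]
  instance$item_states[opt] <- "disabled"
  instance$case_state <- "completed"
  instance$log <- c(instance$log, list(log_record(
    instance$case$case_id, instance$case$case_id, "complete_case", NA_real_)))
  instance
}

#' @rdname complete_case
#' @export
close_case <- function(instance) {
  if (instance$case_state == "closed") sf_immutable_case(instance$case$case_id)
  if (instance$case_state != "completed")
    sf_case_incomplete(instance$case$case_id,
                       "case must be completed before closing")
  instance$case_state <- "closed"
  instance$log <- c(instance$log, list(log_record(
    instance$case$case_id, instance$case$case_id, "close_case", NA_real_)))
  instance
}

#' Active / enabled human tasks of a case instance
#'
#' @param instance A `case_instance`.
#' @param states Lifecycle states to report (default: tasks a user could work
#'   on now, i.e. `active` plus manually startable `enabled` ones).
#' @return Sorted character vector of plan-item ids.
#' @export
case_active_tasks <- function(instance, states = c("active", "enabled")) {
  ids <- names(instance$index)
  hts <- ids[vapply(instance$index, function(e)
    e$item$kind == "human_task", logical(1))]
  sort(hts[instance$item_states[hts] %in% states])
}

#' @export
print.case_instance <- function(x, ...) {
  cat(sprintf("<case_instance> %s (%s)\n", x$case$case_id, x$case_state))
  cat(sprintf("  trace: %s\n",
              if (length(x$trace)) paste(x$trace, collapse = " > ") else "(empty)"))
  cat(sprintf("  active/enabled: %s\n",
              paste(case_active_tasks(x), collapse = ", ")))
  invisible(x)
}
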