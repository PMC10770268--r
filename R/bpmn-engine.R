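# Token engine for the supported BPMN subset.
#
# The instance keeps the set of completed / bypassed tasks and the committed
# decision of every exclusive gateway; the set of currently activatable tasks
# is derived from the block tree.  Completing a task commits all silent moves
# needed to reach it: bypassable blocks before it are skipped, the exclusive
# gateway of its branch is resolved (marking sibling branches bypassed), and
# -- under engine-compatibility mode -- undecided optional guards in sibling
# parallel branches are bypassed as well.

#' Start a process instance
#'
#' Advances the token from the start event until it rests on user tasks:
#' parallel gateways activate all branches, exclusive gateways leave a pending
#' decision whose branch-first tasks are reported as activatable.
#'
#' @param model A [process_model()].
#' @param camunda_compat Logical.  When `TRUE` (the default, matching the
#'   workflow-engine behavior this package reproduces), an undecided optional
#'   task inside a parallel block is bypassed as soon as a task in a sibling
#'   branch completes, so the optional can no longer be done late.  When
#'   `FALSE` the optional stays activatable until the parallel join is passed.
#' @param clock Initial elapsed time in minutes.
#' @return A `process_instance`.
#' @export
start_process <- function(model, camunda_compat = TRUE, clock = 0) {
  validate_process_model(model)
  kinds <- vapply(model$nodes, `[[`, character(1), "kind")
  if (!any(kinds == "start_event"))
    sf_validation_error(sprintf("process '%s' has no start event", model$model_id))
  tree <- process_tree(model)
  structure(
    list(
      model = model, tree = tree,
      states = stats::setNames(character(0), character(0)),  # completed/bypassed
      choices = list(),                                      # xor id -> branch idx | "bypass"
      trace = character(0), clock = as.numeric(clock),
      compat = isTRUE(camunda_compat),
      log = list()
    ),
    class = "process_instance"
  )
}

task_state_of <- function(inst, id) {
  s <- inst$states[id]
  if (is.na(s)) "inactive" else unname(s)
}

blk_done <- function(b, inst) {
  switch(b$type,
    task = task_state_of(inst, b$id) %in% c("completed", "bypassed"),
    seq = all(vapply(b$children, blk_done, logical(1), inst = inst)),
    subproc = blk_done(b$body, inst),
    and = all(vapply(b$branches, blk_done, logical(1), inst = inst)),
    xor = {
      ch <- inst$choices[[b$id]]
      if (is.null(ch)) FALSE
      else if (identical(ch, "bypass")) TRUE
      else blk_done(b$branches[[ch]], inst)
    }
  )
}

# passable: the token could clear this block without any further task
# completion (everything remaining is bypassable)
blk_passable <- function(b, inst) {
  switch(b$type,
    task = task_state_of(inst, b$id) %in% c("completed", "bypassed"),
    seq = all(vapply(b$children, blk_passable, logical(1), inst = inst)),
    subproc = blk_passable(b$body, inst),
    and = all(vapply(b$branches, blk_passable, logical(1), inst = inst)),
    xor = {
      ch <- inst$choices[[b$id]]
      if (is.null(ch))
        any(vapply(b$branches, blk_passable, logical(1), inst = inst))
      else if (identical(ch, "bypass")) TRUE
      else blk_passable(b$branches[[ch]], inst)
    }
  )
}

blk_activatable <- function(b, inst) {
  switch(b$type,
    task = if (task_state_of(inst, b$id) %in% c("completed", "bypassed"))
      character(0) else b$id,
    seq = {
      out <- character(0)
      for (ch in b$children) {
        if (blk_done(ch, inst)) next
        out <- c(out, blk_activatable(ch, inst))
        if (!blk_passable(ch, inst)) break
      }
      out
    },
    subproc = blk_activatable(b$body, inst),
    and = unlist(lapply(b$branches, function(br)
      if (blk_done(br, inst)) character(0) else blk_activatable(br, inst)),
      use.names = FALSE),
    xor = {
      ch <- inst$choices[[b$id]]
      if (is.null(ch))
        unlist(lapply(b$branches, blk_activatable, inst = inst), use.names = FALSE)
      else if (identical(ch, "bypass")) character(0)
      else blk_activatable(b$branches[[ch]], inst)
    }
  )
}

#' Activatable tasks of a running instance
#'
#' Returns the user tasks (and, at root level of combination models, call
#' activities) the token currently rests on, plus the first task of every
#' branch of a pending exclusive decision, in deterministic lexical order.
#'
#' @param instance A `process_instance`.
#' @return Sorted character vector of node ids.
#' @export
active_tasks <- function(instance) {
  sort(unique(blk_activatable(instance$tree, instance)))
}

#' Has the instance reached an end event?
#'
#' `TRUE` once the token can reach the end event of the root process without
#' any further task completion, i.e. every remaining block is bypassable.
#' A trailing optional task may still be completed on a "complete" instance.
#'
#' @param instance A `process_instance`.
#' @return Logical.
#' @export
is_complete <- function(instance) {
  blk_passable(instance$tree, instance)
}

# mark everything unfinished inside b as bypassed, committing undecided
# exclusive gateways to their bypass branch
commit_bypass <- function(b, env) {
  switch(b$type,
    task = {
      if (!identical(unname(env$states[b$id]), "completed"))
        env$states[b$id] <- "bypassed"
    },
    seq = for (ch in b$children) commit_bypass(ch, env),
    subproc = commit_bypass(b$body, env),
    and = for (br in b$branches) commit_bypass(br, env),
    xor = {
      ch <- env$choices[[b$id]]
      if (is.null(ch)) {
        env$choices[[b$id]] <- "bypass"
        for (br in b$branches) commit_bypass(br, env)
      } else if (!identical(ch, "bypass")) {
        commit_bypass(b$branches[[ch]], env)
      }
    }
  )
  invisible(NULL)
}

commit_complete <- function(b, tid, env, inst_before, act_before, compat) {
  switch(b$type,
    task = {
      env$states[tid] <- "completed"
      if (b$kind == "user_task") env$trace <- c(env$trace, tid)
    },
    seq = {
      idx <- which(vapply(b$children, blk_contains, logical(1), tid = tid))[1]
      for (j in seq_len(idx - 1L)) {
        if (!blk_done(b$children[[j]], inst_before))
          commit_bypass(b$children[[j]], env)
      }
      commit_complete(b$children[[idx]], tid, env, inst_before, act_before, compat)
    },
    subproc = commit_complete(b$body, tid, env, inst_before, act_before, compat),
    and = {
      idx <- which(vapply(b$branches, blk_contains, logical(1), tid = tid))[1]
      commit_complete(b$branches[[idx]], tid, env, inst_before, act_before, compat)
      if (compat) {
        for (j in seq_along(b$branches)) {
          if (j == idx) next
          bypass_frontier_optionals(b$branches[[j]], env, act_before)
        }
      }
    },
    xor = {
      idx <- which(vapply(b$branches, blk_contains, logical(1), tid = tid))[1]
      ch <- env$choices[[b$id]]
      if (is.null(ch)) {
        env$choices[[b$id]] <- idx
        for (j in seq_along(b$branches)) {
          if (j != idx) commit_bypass(b$branches[[j]], env)
        }
      }
      commit_complete(b$branches[[idx]], tid, env, inst_before, act_before, compat)
    }
  )
  invisible(NULL)
}

# engine-compatibility rule: undecided optional guards whose task was on the
# activatable frontier are bypassed once a sibling parallel branch advances
bypass_frontier_optionals <- function(b, env, act_before) {
  switch(b$type,
    xor = {
      if (is.null(env$choices[[b$id]]) && blk_is_optional_guard(b) &&
          any(blk_task_ids(b) %in% act_before)) {
        env$choices[[b$id]] <- "bypass"
        for (br in b$branches) commit_bypass(br, env)
      }
    },
    seq = for (ch in b$children) bypass_frontier_optionals(ch, env, act_before),
    and = for (br in b$branches) bypass_frontier_optionals(br, env, act_before),
    subproc = bypass_frontier_optionals(b$body, env, act_before),
    task = invisible(NULL)
  )
  invisible(NULL)
}

#' Complete a task of a BPMN process instance
#'
#' The task must be activatable.  Completion appends the task to the trace,
#' resolves the exclusive decision of its branch (bypassing sibling
#' branches), silently skips bypassable blocks that precede it, and -- under
#' engine-compatibility mode -- bypasses undecided optional tasks in sibling
#' parallel branches.
#'
#' @param instance A `process_instance`.
#' @param task_id Node id of the task (or call activity) to complete.
#' @param clock Optional new clock value in minutes.
#' @return The updated `process_instance`.
#' @export
complete_task <- function(instance, task_id, clock = NULL) {
  UseMethod("complete_task")
}

#' @export
complete_task.process_instance <- function(instance, task_id, clock = NULL) {
  if (!blk_contains(instance$tree, task_id)) sf_lookup_error(task_id, "task")
  act <- blk_activatable(instance$tree, instance)
  if (!task_id %in% act) {
    st <- task_state_of(instance, task_id)
    if (st == "completed") sf_regression(task_id)
    if (st == "bypassed") sf_bypassed_task(task_id)
    sf_out_of_order(task_id, "task is downstream or not yet activatable")
  }
  env <- new.env(parent = emptyenv())
  env$states <- instance$states
  env$choices <- instance$choices
  env$trace <- instance$trace
  commit_complete(instance$tree, task_id, env, instance, act, instance$compat)
  instance$states <- env$states
  instance$choices <- env$choices
  instance$trace <- env$trace
  if (!is.null(clock)) instance$clock <- as.numeric(clock)
  instance$log <- c(instance$log, list(log_record(
    instance$model$model_id, task_id, "complete", instance$clock)))
  instance
}

#' Full task-state map of an instance
#'
#' @param instance A `process_instance`.
#' @return Named character vector over all task ids with values
#'   `"inactive"`, `"active"`, `"completed"` or `"bypassed"`.
#' @export
task_states <- function(instance) {
  ids <- sort(blk_task_ids(instance$tree))
  act <- active_tasks(instance)
  out <- vapply(ids, function(id) {
    s <- task_state_of(instance, id)
    if (s == "inactive" && id %in% act) "active" else s
  }, character(1))
  out
}

log_record <- function(instance_id, element, transition, clock) {
  list(instance = instance_id, element = element, transition = transition,
       clock = clock)
}

#' @export
print.process_instance <- function(x, ...) {
  cat(sprintf("<process_instance> %s\n", x$model$model_id))
  cat(sprintf("  trace: %s\n",
              if (length(x$trace)) paste(x$trace, collapse = " > ") else "(empty)"))
  cat(sprintf("  activatable: %s\n", paste(active_tasks(x), collapse = ", ")))
  cat(sprintf("  complete: %s, clock: %g min\n", is_complete(x), x$clock))
  invisible(x)
}
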