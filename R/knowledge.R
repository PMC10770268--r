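# Process knowledge derived from the models: next possible steps (static
# graph lookahead and engine-replay refinement), completable running activity
# instances with a reasonableness verdict, and the remaining-surgery-duration
# / delay estimate.
#
# Process knowledge is computed on the BPMN variant of an intervention even
# when a CMMN or combination model is being controlled: the structured model
# stands in for knowledge about similar, already executed cases.

# Per-level lookup across sub-process boundaries.
graph_index <- function(model) {
  env <- new.env(parent = emptyenv())
  env$kind <- character(0)
  env$succ <- list()
  env$owner <- character(0)    # node id -> enclosing sub-process id or ""
  env$sp_entry <- character(0) # sub-process id -> its start event id
  add_level <- function(nodes, flows, owner_id) {
    for (n in nodes) {
      env$kind[n$node_id] <- n$kind
      env$owner[n$node_id] <- owner_id
      if (n$kind == "start_event" && nzchar(owner_id))
        env$sp_entry[owner_id] <- n$node_id
      if (n$kind == "start_event" && !nzchar(owner_id))
        env$root_start <- n$node_id
      if (n$kind == "sub_process") add_level(n$children, n$child_flows, n$node_id)
    }
    for (f in flows) env$succ[[f$source]] <- c(env$succ[[f$source]], f$target)
  }
  add_level(model$nodes, model$flows, "")
  env
}

#' Next possible steps by static model lookahead
#'
#' Recursive traversal of the sequence flows starting from the current step:
#' both gateway kinds expand into every outgoing branch, sub-processes are
#' entered at their start event and left at their end events, and each path
#' terminates at the first task it encounters.
#'
#' @param model A [process_model()].
#' @param current A task id in the model, or the sentinel `"start"` for the
#'   position before the first step.
#' @return Sorted character vector of step ids.
#' @export
static_next_steps <- function(model, current = "start") {
  gi <- graph_index(model)
  if (!identical(current, "start") && is.na(gi$kind[current]))
    sf_lookup_error(current, "step")
  visit <- function(id, seen) {
    if (id %in% seen) return(character(0))
    seen <- c(seen, id)
    kind <- gi$kind[[id]]
    if (kind %in% c("user_task", "call_activity")) return(id)
    if (kind == "sub_process") return(visit(gi$sp_entry[[id]], seen))
    if (kind == "end_event") {
      owner <- gi$owner[[id]]
      if (!nzchar(owner)) return(character(0))
      return(follow_out(owner, seen))
    }
    # start event or gateway: fan out
    follow_out(id, seen)
  }
  follow_out <- function(id, seen) {
    out <- character(0)
    for (t in gi$succ[[id]]) out <- c(out, visit(t, seen))
    out
  }
  from <- if (identical(current, "start")) visit(gi$root_start, character(0))
          else follow_out(current, current)
  sort(unique(from))
}

#' Next possible steps by engine replay
#'
#' Replays a trace prefix on a fresh instance and returns the activatable
#' tasks.  Equals [static_next_steps()] of the last completed step whenever no
#' parallel block is mid-flight.
#'
#' @param model A [process_model()].
#' @param trace Character vector of completed step ids (a valid prefix).
#' @param camunda_compat Engine-compatibility flag, see [start_process()].
#' @return Sorted character vector of activatable step ids.
#' @export
dynamic_next_steps <- function(model, trace = character(0), camunda_compat = TRUE) {
  inst <- replay_trace(model, trace, camunda_compat)
  active_tasks(inst)
}

replay_trace <- function(model, trace, camunda_compat = TRUE) {
  inst <- start_process(model, camunda_compat = camunda_compat)
  for (t in trace) {
    inst <- tryCatch(
      complete_task(inst, t),
      surgflow_error = function(e) sf_abort(
        sprintf("trace is not a valid prefix at '%s': %s", t, conditionMessage(e)),
        class = "surgflow_replay_error")
    )
  }
  inst
}

#' Completable running instances and reasonableness of a candidate situation
#'
#' For a candidate next situation, the completable list holds every running
#' activity instance whose static next steps contain the candidate
#' (completing those activates the candidate).  The candidate is reasonable
#' when it is activatable after the trace so far, or when it repeats the most
#' recently completed step.
#'
#' @param model The BPMN variant used as knowledge source.
#' @param trace Completed step ids so far.
#' @param candidate Candidate step id.
#' @param running Character vector of currently running activity instance ids
#'   (the engine's active set).
#' @param camunda_compat Engine-compatibility flag.
#' @return A `process_knowledge` list with fields `next_steps`, `completable`,
#'   `reasonable` and `source_model`.
#' @export
completable_instances <- function(model, trace, candidate, running,
                                  camunda_compat = TRUE) {
  # a trace driven on a more permissive model may not replay on this one;
  # degrade to "no next-step knowledge" rather than failing
  nxt <- tryCatch(dynamic_next_steps(model, trace, camunda_compat),
                  surgflow_error = function(e) character(0))
  known <- candidate %in% blk_task_ids(process_tree(model))
  completable <- character(0)
  if (known) {
    for (t in running) {
      if (candidate %in% static_next_steps(model, t))
        completable <- c(completable, t)
    }
  }
  reasonable <- known && (candidate %in% nxt ||
    (length(trace) > 0 && identical(candidate, trace[[length(trace)]])))
  structure(
    list(next_steps = nxt, completable = completable,
         reasonable = reasonable, source_model = model$model_id),
    class = "process_knowledge"
  )
}

#' Remaining surgery duration and delay
#'
#' Pure process-knowledge estimate: the remaining duration is the sum of the
#' expected durations of required steps not yet completed (optional steps are
#' excluded; an unresolved exclusive decision contributes its
#' maximum-duration branch, a resolved one the remainder of the chosen
#' branch).  The delay is the elapsed clock minus the expected elapsed time
#' over the completed trace.
#'
#' @param model A [process_model()] whose main-path tasks carry durations.
#' @param trace Completed step ids.
#' @param clock Elapsed minutes.
#' @param camunda_compat Engine-compatibility flag for the replay.
#' @return A `duration_estimate` list with `available`, `rsd`, `delay` and
#'   `expected_elapsed` (all `NA` when durations are missing from the model).
#' @export
remaining_duration <- function(model, trace = character(0), clock = 0,
                               camunda_compat = TRUE) {
  inst <- tryCatch(replay_trace(model, trace, camunda_compat),
                   surgflow_error = function(e) NULL)
  if (is.null(inst)) {
    return(structure(
      list(available = FALSE, rsd = NA_real_, delay = NA_real_,
           expected_elapsed = NA_real_),
      class = "duration_estimate"
    ))
  }
  rsd <- blk_rsd(inst$tree, inst)
  durs <- task_durations(model)
  elapsed <- if (length(trace)) sum(durs[trace]) else 0
  if (is.na(rsd) || is.na(elapsed)) {
    return(structure(
      list(available = FALSE, rsd = NA_real_, delay = NA_real_,
           expected_elapsed = NA_real_),
      class = "duration_estimate"
    ))
  }
  structure(
    list(available = TRUE, rsd = rsd, delay = as.numeric(clock) - elapsed,
         expected_elapsed = elapsed),
    class = "duration_estimate"
  )
}

task_durations <- function(model) {
  nodes <- all_nodes_flat(model)
  tasks <- nodes[vapply(nodes, `[[`, character(1), "kind") == "user_task"]
  stats::setNames(vapply(tasks, `[[`, numeric(1), "expected_duration"),
                  vapply(tasks, `[[`, character(1), "node_id"))
}

blk_rsd <- function(b, inst) {
  switch(b$type,
    task = {
      if (blk_done(b, inst)) 0
      else if (is.na(b$duration)) NA_real_
      else b$duration
    },
    seq = sum(vapply(b$children, blk_rsd, numeric(1), inst = inst)),
    subproc = blk_rsd(b$body, inst),
    and = sum(vapply(b$branches, blk_rsd, numeric(1), inst = inst)),
    xor = {
      ch <- inst$choices[[b$id]]
      if (!is.null(ch)) {
        if (identical(ch, "bypass")) 0 else blk_rsd(b$branches[[ch]], inst)
      } else if (blk_is_optional_guard(b)) {
        0  # optional steps are excluded from the estimate
      } else {
        max(vapply(b$branches, blk_rsd, numeric(1), inst = inst))
      }
    }
  )
}
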