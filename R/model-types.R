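# In-memory representations of the supported BPMN / CMMN subsets.
#
# A process model is a flat node/flow graph per level; sub-processes carry
# their own nested nodes and flows.  A case model is a tree of plan items
# rooted at the case plan model.  Both are plain S3 lists so they serialize
# and compare structurally (round-trip tests rely on exact equality).

BPMN_NODE_KINDS <- c("user_task", "xor_gateway", "and_gateway", "start_event",
                     "end_event", "sub_process", "call_activity",
                     "signal_boundary_event")

CMMN_ITEM_KINDS <- c("human_task", "stage", "event_listener")

#' Create a BPMN flow node
#'
#' Flow nodes are the vertices of a process level: user tasks, gateways,
#' events, sub-processes and call activities.  Sub-processes nest their own
#' node/flow graph via `children` and `child_flows`.
#'
#' @param node_id Unique identifier within the model.
#' @param kind One of `r paste0('"', BPMN_NODE_KINDS, '"', collapse = ", ")`.
#' @param name Human-readable label (may be empty).
#' @param optional_step Logical; marks a task that the process may bypass
#'   (rendered as an XOR gateway pair with a bypass branch).
#' @param expected_duration Expected duration in minutes, or `NA` when not
#'   modeled.
#' @param children,child_flows Nested graph for `sub_process` nodes.
#' @param called_case Referenced case id (only for `call_activity`).
#' @param attached_to Host node id (only for `signal_boundary_event`).
#' @return A `flow_node` list.
#' @export
flow_node <- function(node_id, kind, name = "", optional_step = FALSE,
                      expected_duration = NA_real_, children = list(),
                      child_flows = list(), called_case = NA_character_,
                      attached_to = NA_character_) {
  kind <- match.arg(kind, BPMN_NODE_KINDS)
  structure(
    list(
      node_id = as.character(node_id), kind = kind, name = as.character(name),
      optional_step = isTRUE(optional_step),
      expected_duration = as.numeric(expected_duration),
      children = children, child_flows = child_flows,
      called_case = as.character(called_case),
      attached_to = as.character(attached_to)
    ),
    class = "flow_node"
  )
}

#' Create a sequence flow
#'
#' @param flow_id Unique flow identifier.
#' @param source,target Node ids the flow connects.
#' @param label Branch label for XOR decisions (may be empty).
#' @return A `sequence_flow` list.
#' @export
sequence_flow <- function(flow_id, source, target, label = "") {
  structure(
    list(flow_id = as.character(flow_id), source = as.character(source),
         target = as.character(target), label = as.character(label)),
    class = "sequence_flow"
  )
}

#' Create a BPMN process model
#'
#' @param model_id,name Identifier and label of the process.
#' @param nodes List of [flow_node()] objects (root level).
#' @param flows List of [sequence_flow()] objects (root level).
#' @param granularity `"one_level"` for a flat step model, `"two_level"` when
#'   steps are grouped into phase sub-processes.
#' @param validate Run [validate_process_model()] on the result.
#' @return A `process_model` object.
#' @export
process_model <- function(model_id, name = model_id, nodes = list(),
                          flows = list(), granularity = c("one_level", "two_level"),
                          validate = TRUE) {
  granularity <- match.arg(granularity)
  m <- structure(
    list(model_id = as.character(model_id), name = as.character(name),
         nodes = name_by(nodes, "node_id"), flows = flows,
         granularity = granularity),
    class = "process_model"
  )
  if (validate) validate_process_model(m)
  m
}

#' Create a CMMN sentry (entry criterion)
#'
#' Only the `"complete"` standard event is supported: an item guarded by a
#' sentry becomes available for activation once every referenced source item
#' has completed.
#'
#' @param sentry_id Identifier.
#' @param sources Character vector of plan-item ids whose completion satisfies
#'   the sentry.
#' @return A `sentry` list with one on-part per source.
#' @export
sentry <- function(sentry_id, sources) {
  structure(
    list(sentry_id = as.character(sentry_id),
         on_parts = lapply(as.character(sources), function(s)
           list(source = s, event = "complete"))),
    class = "sentry"
  )
}

#' Create a CMMN plan item
#'
#' The optionality convention follows the case models this package targets:
#' an optional step is encoded as `required = FALSE` together with
#' `manual_activation = TRUE`; required steps activate automatically.
#'
#' @param item_id Identifier.
#' @param kind `"human_task"`, `"stage"` or `"event_listener"`.
#' @param name Label.
#' @param required Logical; required items must complete before their stage or
#'   case can complete.
#' @param manual_activation Logical; manually activated items wait in state
#'   `enabled` until started.
#' @param entry_criteria List of [sentry()] objects.
#' @param children Child plan items (stages only).
#' @param expected_duration Minutes, or `NA`.
#' @return A `plan_item` list.
#' @export
plan_item <- function(item_id, kind, name = "", required = TRUE,
                      manual_activation = FALSE, entry_criteria = list(),
                      children = list(), expected_duration = NA_real_) {
  kind <- match.arg(kind, CMMN_ITEM_KINDS)
  structure(
    list(item_id = as.character(item_id), kind = kind, name = as.character(name),
         required = isTRUE(required), manual_activation = isTRUE(manual_activation),
         entry_criteria = entry_criteria, children = name_by(children, "item_id"),
         expected_duration = as.numeric(expected_duration)),
    class = "plan_item"
  )
}

#' Create a CMMN case model
#'
#' @param case_id,name Identifier and label.
#' @param plan_items Plan items directly under the case plan model.
#' @param validate Run [validate_case_model()].
#' @return A `case_model` object.
#' @export
case_model <- function(case_id, name = case_id, plan_items = list(),
                       validate = TRUE) {
  m <- structure(
    list(case_id = as.character(case_id), name = as.character(name),
         plan_items = name_by(plan_items, "item_id")),
    class = "case_model"
  )
  if (validate) validate_case_model(m)
  m
}

#' Create a BPMN+CMMN combination model
#'
#' @param style `"structured"` (root process holds only phase shells and call
#'   activities) or `"mixed"` (root process mixes user tasks with call
#'   activities).
#' @param root The root [process_model()].
#' @param cases Named list of [case_model()] objects keyed by case id.
#' @param validate Check call-activity references and style constraints.
#' @return A `combination_model` object.
#' @export
combination_model <- function(style = c("structured", "mixed"), root, cases,
                              validate = TRUE) {
  style <- match.arg(style)
  m <- structure(list(style = style, root = root, cases = cases),
                 class = "combination_model")
  if (validate) validate_combination_model(m)
  m
}

name_by <- function(xs, field) {
  if (length(xs) == 0) return(structure(list(), names = character(0)))
  stats::setNames(xs, vapply(xs, function(x) x[[field]], character(1)))
}

# Validation ----------------------------------------------------------------

all_nodes_flat <- function(model) {
  walk <- function(nodes) {
    out <- list()
    for (n in nodes) {
      out[[length(out) + 1L]] <- n
      if (length(n$children)) out <- c(out, walk(n$children))
    }
    out
  }
  walk(model$nodes)
}

validate_level <- function(nodes, flows, where) {
  ids <- vapply(nodes, `[[`, character(1), "node_id")
  if (anyDuplicated(ids))
    sf_validation_error(sprintf("duplicate node ids in %s: %s", where,
                                paste(ids[duplicated(ids)], collapse = ", ")))
  kinds <- vapply(nodes, `[[`, character(1), "kind")
  n_start <- sum(kinds == "start_event")
  n_end <- sum(kinds == "end_event")
  if (n_start != 1L)
    sf_validation_error(sprintf("%s must contain exactly one start event (found %d)",
                                where, n_start))
  if (n_end < 1L)
    sf_validation_error(sprintf("%s must contain at least one end event", where))
  for (f in flows) {
    if (!(f$source %in% ids) || !(f$target %in% ids))
      sf_validation_error(sprintf(
        "flow '%s' in %s references unknown node ('%s' -> '%s')",
        f$flow_id, where, f$source, f$target))
  }
  # boundary events attach to tasks or sub-processes only
  for (n in nodes) {
    if (n$kind == "signal_boundary_event") {
      host <- nodes[[match(n$attached_to, ids)]]
      if (is.null(host) || !host$kind %in% c("user_task", "sub_process"))
        sf_validation_error(sprintf(
          "boundary event '%s' must attach to a task or sub-process", n$node_id))
    }
  }
  # reachability from the start event (boundary events excluded: they attach,
  # they are not flow targets)
  start_id <- ids[kinds == "start_event"]
  adj <- split(vapply(flows, `[[`, character(1), "target"),
               vapply(flows, `[[`, character(1), "source"))
  seen <- character(0); queue <- start_id
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    if (v %in% seen) next
    seen <- c(seen, v)
    queue <- c(queue, adj[[v]])
  }
  flow_nodes <- ids[!kinds %in% "signal_boundary_event"]
  unreachable <- setdiff(flow_nodes, seen)
  if (length(unreachable))
    sf_validation_error(sprintf("nodes unreachable from start event in %s: %s",
                                where, paste(unreachable, collapse = ", ")))
  invisible(TRUE)
}

#' Validate a process model
#'
#' Checks the structural invariants of the supported subset: one start event
#' and at least one end event per level, resolvable flow references, unique
#' ids, reachability from the start event, and legal boundary-event
#' attachment.  Recurses into sub-processes.
#'
#' @param model A `process_model`.
#' @return Invisibly `TRUE`; signals a `surgflow_validation_error` otherwise.
#' @export
validate_process_model <- function(model) {
  if (!inherits(model, "process_model"))
    sf_validation_error("not a process_model")
  validate_level(model$nodes, model$flows, sprintf("process '%s'", model$model_id))
  for (n in model$nodes) {
    if (n$kind == "sub_process") {
      if (!length(n$children))
        sf_validation_error(sprintf("sub-process '%s' has no children", n$node_id))
      validate_level(n$children, n$child_flows,
                     sprintf("sub-process '%s'", n$node_id))
    } else if (length(n$children)) {
      sf_validation_error(sprintf("non-sub-process node '%s' has children", n$node_id))
    }
  }
  all_ids <- vapply(all_nodes_flat(model), `[[`, character(1), "node_id")
  if (anyDuplicated(all_ids))
    sf_validation_error(sprintf("node ids duplicated across levels: %s",
                                paste(unique(all_ids[duplicated(all_ids)]), collapse = ", ")))
  invisible(TRUE)
}

flatten_items <- function(items) {
  out <- list()
  for (it in items) {
    out[[length(out) + 1L]] <- it
    if (length(it$children)) out <- c(out, flatten_items(it$children))
  }
  out
}

#' Validate a case model
#'
#' Plan-item ids must be unique, sentries may only reference existing items
#' with the `"complete"` standard event, only stages may nest children, and
#' optional items must follow the `required = FALSE` +
#' `manual_activation = TRUE` convention.
#'
#' @param case A `case_model`.
#' @return Invisibly `TRUE`; signals a `surgflow_validation_error` otherwise.
#' @export
validate_case_model <- function(case) {
  if (!inherits(case, "case_model")) sf_validation_error("not a case_model")
  items <- flatten_items(case$plan_items)
  ids <- vapply(items, `[[`, character(1), "item_id")
  if (anyDuplicated(ids))
    sf_validation_error(sprintf("duplicate plan-item ids: %s",
                                paste(ids[duplicated(ids)], collapse = ", ")))
  for (it in items) {
    if (it$kind != "stage" && length(it$children))
      sf_validation_error(sprintf("non-stage item '%s' has children", it$item_id))
    for (s in it$entry_criteria) {
      for (op in s$on_parts) {
        if (!op$source %in% ids)
          sf_validation_error(sprintf(
            "sentry '%s' on item '%s' references unknown item '%s'",
            s$sentry_id, it$item_id, op$source))
        if (!identical(op$event, "complete"))
          sf_abort(sprintf("sentry '%s': unsupported standard event '%s'",
                           s$sentry_id, op$event),
                   class = "surgflow_unsupported_rule")
      }
    }
    if (!it$required && it$kind == "human_task" && !it$manual_activation)
      sf_validation_error(sprintf(
        "optional item '%s' must carry a manual activation rule", it$item_id))
  }
  invisible(TRUE)
}

#' Validate a combination model
#'
#' @param model A `combination_model`.
#' @return Invisibly `TRUE`.
#' @export
validate_combination_model <- function(model) {
  validate_process_model(model$root)
  for (cs in model$cases) validate_case_model(cs)
  for (n in all_nodes_flat(model$root)) {
    if (n$kind == "call_activity" && !n$called_case %in% names(model$cases))
      sf_validation_error(sprintf(
        "call activity '%s' references unknown case '%s'", n$node_id, n$called_case))
    if (model$style == "structured" && n$kind == "user_task")
      sf_validation_error(sprintf(
        "structured combination root may not contain user tasks ('%s')", n$node_id))
  }
  invisible(TRUE)
}

# Small accessors used everywhere -------------------------------------------

#' List the user-task ids of a process model (all levels)
#' @param model A `process_model`.
#' @return Character vector of task ids in document order.
#' @export
model_task_ids <- function(model) {
  nodes <- all_nodes_flat(model)
  vapply(nodes[vapply(nodes, `[[`, character(1), "kind") == "user_task"],
         `[[`, character(1), "node_id")
}

#' List the human-task ids of a case model (all stages)
#' @param case A `case_model`.
#' @return Character vector of task ids in document order.
#' @export
case_task_ids <- function(case) {
  items <- flatten_items(case$plan_items)
  vapply(items[vapply(items, `[[`, character(1), "kind") == "human_task"],
         `[[`, character(1), "item_id")
}

#' @export
print.process_model <- function(x, ...) {
  nodes <- all_nodes_flat(x)
  kinds <- vapply(nodes, `[[`, character(1), "kind")
  cat(sprintf("<process_model> %s (%s)\n", x$model_id, x$granularity))
  cat(sprintf("  %d nodes (%d user tasks, %d sub-processes), %d root flows\n",
              length(nodes), sum(kinds == "user_task"),
              sum(kinds == "sub_process"), length(x$flows)))
  invisible(x)
}

#' @export
print.case_model <- function(x, ...) {
  items <- flatten_items(x$plan_items)
  kinds <- vapply(items, `[[`, character(1), "kind")
  cat(sprintf("<case_model> %s\n", x$case_id))
  cat(sprintf("  %d plan items (%d human tasks, %d stages)\n",
              length(items), sum(kinds == "human_task"), sum(kinds == "stage")))
  invisible(x)
}

#' @export
print.combination_model <- function(x, ...) {
  cat(sprintf("<combination_model> style=%s, root=%s, %d case(s)\n",
              x$style, x$root$model_id, length(x$cases)))
  invisible(x)
}
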