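# Classed conditions used across the package. Every error a caller might want
# to branch on (validation, unsupported element, engine lifecycle, ...) gets a
# dedicated subclass of "surgflow_error" so tests and the controller can catch
# precisely.

sf_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "surgflow_error", "error")))
}

#' @noRd
sf_validation_error <- function(message, ...) {
  sf_abort(message, class = "surgflow_validation_error", ...)
}

sf_parse_error <- function(message, ...) {
  sf_abort(message, class = "surgflow_parse_error", ...)
}

sf_unsupported_element <- function(elements, where) {
  sf_abort(
    sprintf(
      "unsupported element%s in %s: %s",
      if (length(elements) > 1) "s" else "", where,
      paste(sort(unique(elements)), collapse = ", ")
    ),
    class = "surgflow_unsupported_element",
    elements = sort(unique(elements))
  )
}

sf_lookup_error <- function(id, what = "element") {
  sf_abort(sprintf("unknown %s id: %s", what, id), class = "surgflow_lookup_error")
}

# BPMN engine refusals ------------------------------------------------------

sf_out_of_order <- function(task, why = "task is not active or activatable") {
  sf_abort(sprintf("cannot complete '%s': %s", task, why),
           class = "surgflow_out_of_order", task = task)
}

sf_regression <- function(task) {
  sf_abort(sprintf("cannot complete '%s': task already completed", task),
           class = c("surgflow_regression"), task = task)
}

sf_bypassed_task <- function(task) {
  # late optional under engine-compatible bypass: a refusal subclass of
  # out-of-order so generic handlers still work
  stop(errorCondition(
    sprintf("cannot complete '%s': optional task was already bypassed", task),
    task = task,
    class = c("surgflow_bypassed_task", "surgflow_out_of_order",
              "surgflow_error", "error")
  ))
}

# CMMN lifecycle refusals ---------------------------------------------------

sf_lifecycle_error <- function(item, state, wanted) {
  sf_abort(
    sprintf("plan item '%s' is '%s', expected '%s'", item, state,
            paste(wanted, collapse = "' or '")),
    class = "surgflow_lifecycle_error", item = item, state = state
  )
}

sf_stage_incomplete <- function(stage, missing) {
  sf_abort(
    sprintf("stage '%s' has incomplete required children: %s",
            stage, paste(missing, collapse = ", ")),
    class = "surgflow_stage_incomplete", stage = stage, missing = missing
  )
}

sf_stage_busy <- function(stage, active) {
  sf_abort(
    sprintf("stage '%s' still has active children: %s",
            stage, paste(active, collapse = ", ")),
    class = "surgflow_stage_busy", stage = stage, active = active
  )
}

sf_case_incomplete <- function(case_id, missing) {
  sf_abort(
    sprintf("case '%s' has incomplete required items: %s",
            case_id, paste(missing, collapse = ", ")),
    class = "surgflow_case_incomplete", missing = missing
  )
}

sf_immutable_case <- function(case_id) {
  sf_abort(sprintf("case '%s' is closed and accepts no transitions", case_id),
           class = "surgflow_immutable_case")
}
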