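# Brute-force enumeration of accepted complete traces for small models: the
# independent oracle for both engines and for path-count claims.
#
# The BPMN oracle generates trace sets combinatorially over the block tree
# (sequence concatenation, exclusive union, parallel interleaving) and, under
# engine-compatibility mode, filters interleavings against the
# frontier-optional bypass rule.  The CMMN oracle recurses directly on the
# sentry graph with an explicit stage-closure move.  Neither shares the
# engines' token / lifecycle machinery.

#' Closed-form trace count of a variable-order block
#'
#' A block of `k` required tasks in variable order plus `m` optional tasks
#' accepts `sum_j C(m, j) * (k + j)!` distinct complete traces (choose the
#' optional subset, then order freely).
#'
#' @param k Number of required tasks.
#' @param m Number of optional tasks.
#' @return Trace count.
#' @export
variable_block_trace_count <- function(k, m) {
  j <- 0:m
  sum(choose(m, j) * factorial(k + j))
}

#' Enumerate the accepted complete traces of a model
#'
#' Exhaustive expansion of all legal completion orders under the model's
#' semantics; BPMN token rules (including optional bypass) for process
#' models, plan-item lifecycle rules for case models.
#'
#' @param x A [process_model()] or [case_model()].
#' @param limit Maximum number of traces to enumerate; beyond it the result
#'   is flagged truncated.
#' @param camunda_compat For process models: enumerate under the
#'   frontier-optional bypass rule (see [start_process()]).  Default `FALSE`:
#'   the full semantics without the engine peculiarity.
#' @return A `trace_set`: list with `traces` (list of character vectors) and
#'   `truncated`.
#' @export
enumerate_traces <- function(x, limit = 10000L, camunda_compat = FALSE) {
  UseMethod("enumerate_traces")
}

trace_set <- function(traces, truncated = FALSE) {
  structure(list(traces = traces, truncated = truncated), class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d trace(s)%s\n", length(x$traces),
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

dedupe_traces <- function(traces) {
  keys <- vapply(traces, paste, character(1), collapse = "\x1f")
  traces[!duplicated(keys)]
}

# BPMN -----------------------------------------------------------------------

cross_concat <- function(A, B, cap) {
  out <- vector("list", min(length(A) * length(B), cap))
  k <- 0L
  for (a in A) {
    for (b in B) {
      if (k >= cap) return(out[seq_len(k)])
      k <- k + 1L
      out[[k]] <- c(a, b)
    }
  }
  out[seq_len(k)]
}

interleavings <- function(vs, cap) {
  vs <- vs[lengths(vs) > 0]
  if (!length(vs)) return(list(character(0)))
  rec <- function(vs) {
    if (length(vs) == 1L) return(list(vs[[1]]))
    total <- sum(lengths(vs))
    out <- list()
    for (i in seq_along(vs)) {
      head <- vs[[i]][[1]]
      rest <- vs
      if (length(rest[[i]]) == 1L) rest[[i]] <- NULL
      else rest[[i]] <- rest[[i]][-1]
      for (tail in rec(rest)) {
        out[[length(out) + 1L]] <- c(head, tail)
        if (length(out) >= cap) return(out)
      }
    }
    out
  }
  rec(vs)
}

oracle_gen_bpmn <- function(b, cap) {
  switch(b$type,
    task = if (b$kind == "user_task") list(b$id) else
      sf_validation_error("trace oracle does not support call activities"),
    seq = {
      sets <- lapply(b$children, oracle_gen_bpmn, cap = cap)
      Reduce(function(A, B) cross_concat(A, B, cap), sets,
             accumulate = FALSE) %||% list(character(0))
    },
    subproc = oracle_gen_bpmn(b$body, cap),
    xor = dedupe_traces(do.call(c, lapply(b$branches, oracle_gen_bpmn, cap = cap))),
    and = {
      branch_sets <- lapply(b$branches, oracle_gen_bpmn, cap = cap)
      out <- list(); done <- FALSE
      pick <- function(i, chosen) {
        if (done) return(invisible(NULL))
        if (i > length(branch_sets)) {
          for (tr in interleavings(chosen, cap)) {
            out[[length(out) + 1L]] <<- tr
            if (length(out) >= cap) {
              done <<- TRUE
              return(invisible(NULL))
            }
          }
          return(invisible(NULL))
        }
        for (choice in branch_sets[[i]]) pick(i + 1L, c(chosen, list(choice)))
      }
      pick(1L, list())
      dedupe_traces(out)
    }
  )
}

# metadata for the engine-compatibility filter: for every parallel block, the
# ordered task list per branch and the optional tasks it guards
collect_and_meta <- function(b, acc = list()) {
  if (b$type == "and") {
    branch_tasks <- lapply(b$branches, blk_task_ids)
    optionals <- list()
    for (i in seq_along(b$branches)) {
      find_opts <- function(x, preds) {
        if (x$type == "xor" && blk_is_optional_guard(x)) {
          for (tid in blk_task_ids(x)) {
            optionals[[length(optionals) + 1L]] <<- list(
              task = tid, branch = i, preds = preds)
          }
          return(invisible(NULL))
        }
        if (x$type == "seq") {
          p <- preds
          for (ch in x$children) {
            find_opts(ch, p)
            p <- c(p, blk_task_ids(ch))
          }
        } else if (x$type == "subproc") find_opts(x$body, preds)
        else if (x$type %in% c("and", "xor"))
          for (br in x$branches) find_opts(br, preds)
        invisible(NULL)
      }
      find_opts(b$branches[[i]], character(0))
    }
    acc[[length(acc) + 1L]] <- list(id = b$id, branch_tasks = branch_tasks,
                                    optionals = optionals)
  }
  kids <- switch(b$type, seq = b$children, subproc = list(b$body),
                 and = b$branches, xor = b$branches, list())
  for (k in kids) acc <- collect_and_meta(k, acc)
  acc
}

compat_trace_ok <- function(trace, and_meta) {
  pos <- stats::setNames(seq_along(trace), trace)
  for (X in and_meta) {
    for (o in X$optionals) {
      p <- pos[o$task]
      if (is.na(p)) next
      preds_pos <- pos[o$preds]
      q <- if (length(preds_pos) && any(!is.na(preds_pos)))
        max(preds_pos, na.rm = TRUE) else 0
      others <- unlist(X$branch_tasks[-o$branch], use.names = FALSE)
      op <- pos[others]
      if (any(!is.na(op) & op > q & op < p)) return(FALSE)
    }
  }
  TRUE
}

#' @export
enumerate_traces.process_model <- function(x, limit = 10000L,
                                           camunda_compat = FALSE) {
  tree <- process_tree(x)
  cap <- limit + 1L
  traces <- dedupe_traces(oracle_gen_bpmn(tree, cap))
  if (camunda_compat) {
    meta <- collect_and_meta(tree)
    traces <- Filter(function(tr) compat_trace_ok(tr, meta), traces)
  }
  truncated <- length(traces) > limit
  trace_set(traces[seq_len(min(length(traces), limit))], truncated)
}

# CMMN -----------------------------------------------------------------------

#' @export
enumerate_traces.case_model <- function(x, limit = 10000L,
                                        camunda_compat = FALSE) {
  idx <- index_case_items(x)
  ids <- names(idx)
  kind <- vapply(idx, function(e) e$item$kind, character(1))
  required <- vapply(idx, function(e) e$item$required, logical(1))
  parent <- vapply(idx, function(e) e$parent, character(1))
  has_opt <- vapply(ids, function(i) {
    if (kind[[i]] != "stage") return(FALSE)
    any(!vapply(idx[[i]]$item$children, `[[`, logical(1), "required"))
  }, logical(1))
  ancestors <- function(i) {
    out <- character(0)
    p <- parent[[i]]
    while (!is.na(p)) {
      out <- c(out, p)
      p <- parent[[p]]
    }
    out
  }
  anc <- lapply(stats::setNames(ids, ids), ancestors)
  req_tasks <- ids[kind == "human_task" & required]

  stage_done <- function(s, completed, closed) {
    kids <- names(idx[[s]]$item$children)
    for (k in kids) {
      it <- idx[[k]]$item
      if (!it$required || it$kind == "event_listener") next
      if (it$kind == "human_task" && !(k %in% completed)) return(FALSE)
      if (it$kind == "stage" && !stage_done(k, completed, closed)) return(FALSE)
    }
    !has_opt[[s]] || s %in% closed
  }
  source_done <- function(src, completed, closed) {
    if (kind[[src]] == "stage") stage_done(src, completed, closed)
    else src %in% completed
  }
  satisfied <- function(i, completed, closed) {
    crit <- idx[[i]]$item$entry_criteria
    if (!length(crit)) return(TRUE)
    any(vapply(crit, function(s)
      all(vapply(s$on_parts, function(op)
        source_done(op$source, completed, closed), logical(1))), logical(1)))
  }
  open_chain <- function(i, completed, closed) {
    for (a in anc[[i]]) {
      if (a %in% closed) return(FALSE)
      if (!satisfied(a, completed, closed)) return(FALSE)
    }
    TRUE
  }

  out <- new.env(parent = emptyenv())
  out$traces <- list()
  out$seen <- new.env(parent = emptyenv())
  out$truncated <- FALSE

  emit <- function(trace) {
    key <- paste(trace, collapse = "\x1f")
    if (!is.null(out$seen[[key]])) return(invisible(NULL))
    if (length(out$traces) >= limit) {
      out$truncated <- TRUE
      return(invisible(NULL))
    }
    out$seen[[key]] <- TRUE
    out$traces[[length(out$traces) + 1L]] <- trace
    invisible(NULL)
  }

  rec <- function(completed, closed, trace) {
    if (out$truncated) return(invisible(NULL))
    if (all(req_tasks %in% completed)) emit(trace)
    for (i in ids) {
      if (kind[[i]] == "human_task" && !(i %in% completed) &&
          satisfied(i, completed, closed) && open_chain(i, completed, closed)) {
        rec(c(completed, i), closed, c(trace, i))
      }
      if (kind[[i]] == "stage" && has_opt[[i]] && !(i %in% closed) &&
          open_chain(i, completed, closed) && satisfied(i, completed, closed) &&
          stage_done(i, completed, c(closed, i))) {
        rec(completed, c(closed, i), trace)
      }
    }
    invisible(NULL)
  }
  rec(character(0), character(0), character(0))
  trace_set(out$traces, out$truncated)
}

#' Count the accepted complete traces of a model
#'
#' Uses the closed form for models that reduce to a single variable-order
#' block; otherwise counts by enumeration.
#'
#' @inheritParams enumerate_traces
#' @return Integer count (`NA` with a warning when enumeration truncates).
#' @export
count_traces <- function(x, limit = 10000L, camunda_compat = FALSE) {
  if (inherits(x, "process_model") && !camunda_compat) {
    km <- single_variable_block_shape(process_tree(x))
    if (!is.null(km)) return(variable_block_trace_count(km$k, km$m))
  }
  ts <- enumerate_traces(x, limit, camunda_compat)
  if (ts$truncated) {
    warning("trace enumeration truncated at limit; count is a lower bound")
    return(NA_integer_)
  }
  length(ts$traces)
}

# detect seq([subproc(] and-block of single-task branches [)]) shapes
single_variable_block_shape <- function(tree) {
  b <- tree
  repeat {
    if (b$type == "seq" && length(b$children) == 1L) {
      b <- b$children[[1]]
    } else if (b$type == "subproc") {
      b <- b$body
    } else break
  }
  if (b$type != "and") return(NULL)
  k <- 0L; m <- 0L
  for (br in b$branches) {
    inner <- br
    if (inner$type == "seq" && length(inner$children) == 1L)
      inner <- inner$children[[1]]
    if (inner$type == "task") k <- k + 1L
    else if (inner$type == "xor" && blk_is_optional_guard(inner) &&
             length(blk_task_ids(inner)) == 1L) m <- m + 1L
    else return(NULL)
  }
  list(k = k, m = m)
}

# Engine-side enumeration (dual route for the equivalence tests) -------------

engine_trace_set <- function(x, limit = 10000L, camunda_compat = TRUE) {
  if (inherits(x, "process_model")) {
    engine_traces_bpmn(x, limit, camunda_compat)
  } else if (inherits(x, "case_model")) {
    engine_traces_cmmn(x, limit)
  } else sf_validation_error("unsupported model type")
}

engine_traces_bpmn <- function(model, limit, camunda_compat) {
  task_ids <- model_task_ids(model)
  out <- new.env(parent = emptyenv())
  out$traces <- list(); out$truncated <- FALSE
  rec <- function(inst) {
    if (out$truncated) return(invisible(NULL))
    if (is_complete(inst)) {
      if (length(out$traces) >= limit) {
        out$truncated <- TRUE
        return(invisible(NULL))
      }
      out$traces[[length(out$traces) + 1L]] <- inst$trace
    }
    for (t in intersect(active_tasks(inst), task_ids)) {
      rec(complete_task(inst, t))
    }
    invisible(NULL)
  }
  rec(start_process(model, camunda_compat = camunda_compat))
  trace_set(dedupe_traces(out$traces), out$truncated)
}

engine_traces_cmmn <- function(case, limit) {
  out <- new.env(parent = emptyenv())
  out$traces <- list()
  out$seen <- new.env(parent = emptyenv())
  out$truncated <- FALSE
  emit <- function(trace) {
    key <- paste(trace, collapse = "\x1f")
    if (!is.null(out$seen[[key]])) return(invisible(NULL))
    if (length(out$traces) >= limit) {
      out$truncated <- TRUE
      return(invisible(NULL))
    }
    out$seen[[key]] <- TRUE
    out$traces[[length(out$traces) + 1L]] <- trace
  }
  can_finish <- function(ci) {
    for (hop in seq_len(25L)) {
      stages <- names(ci$index)[vapply(names(ci$index), function(i)
        ci$index[[i]]$item$kind == "stage" && item_state(ci, i) == "active",
        logical(1))]
      progressed <- FALSE
      for (s in stages) {
        ci2 <- tryCatch(complete_stage(ci, s), surgflow_error = function(e) NULL)
        if (!is.null(ci2)) {
          ci <- ci2; progressed <- TRUE; break
        }
      }
      if (!progressed) break
    }
    !inherits(tryCatch(complete_case(ci), surgflow_error = function(e) e),
              "condition")
  }
  rec <- function(ci, visited_keys) {
    if (out$truncated) return(invisible(NULL))
    if (can_finish(ci)) emit(ci$trace)
    # task completions
    for (t in case_active_tasks(ci)) {
      ci2 <- ci
      if (item_state(ci2, t) == "enabled") ci2 <- manually_start(ci2, t)
      rec(complete_task(ci2, t), visited_keys)
    }
    # explicit stage completions (they disable optionals: changes the future)
    stages <- names(ci$index)[vapply(names(ci$index), function(i)
      ci$index[[i]]$item$kind == "stage" && item_state(ci, i) == "active",
      logical(1))]
    for (s in stages) {
      ci2 <- tryCatch(complete_stage(ci, s), surgflow_error = function(e) NULL)
      if (is.null(ci2)) next
      key <- paste(c(ci2$trace, "|", ci2$item_states), collapse = "\x1f")
      if (key %in% visited_keys) next
      rec(ci2, c(visited_keys, key))
    }
    invisible(NULL)
  }
  rec(start_case(case), character(0))
  trace_set(out$traces, out$truncated)
}
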