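# Block-structure detection: convert the flat node/flow graph of a process
# level into a single-entry/single-exit block tree (sequences, parallel and
# exclusive blocks, sub-processes, task leaves).  The engines, the duration
# model and parts of the oracle operate on this tree.
#
# Only well-structured graphs are supported: every split gateway must have a
# matching join of the same kind reached by all of its branches.  Boundary
# events are not part of the flow and are dropped here (they round-trip
# through model IO but have no runtime semantics).

blk <- function(type, ...) structure(list(type = type, ...), class = "sf_block")

process_tree <- function(model) {
  blk("seq", id = model$model_id, children = parse_level_tree(model$nodes, model$flows))
}

parse_level_tree <- function(nodes, flows) {
  ids <- vapply(nodes, `[[`, character(1), "node_id")
  node_by_id <- stats::setNames(nodes, ids)
  out_flows <- split(flows, vapply(flows, `[[`, character(1), "source"))
  in_deg <- table(vapply(flows, `[[`, character(1), "target"))
  kinds <- stats::setNames(vapply(nodes, `[[`, character(1), "kind"), ids)
  start_id <- ids[kinds == "start_event"]

  succ <- function(id) {
    fl <- out_flows[[id]]
    if (is.null(fl)) character(0) else vapply(fl, `[[`, character(1), "target")
  }
  indeg <- function(id) if (id %in% names(in_deg)) as.integer(in_deg[[id]]) else 0L

  # walk from `id`, collecting blocks, until hitting an end event or a join
  # gateway belonging to an enclosing split; returns list(blocks, stop).
  walk <- function(id) {
    blocks <- list()
    repeat {
      kind <- kinds[[id]]
      if (kind == "start_event") {
        id <- succ(id)[[1]]
        next
      }
      if (kind == "end_event") return(list(blocks = blocks, stop = NULL))
      if (kind %in% c("user_task", "call_activity")) {
        n <- node_by_id[[id]]
        blocks[[length(blocks) + 1L]] <- blk(
          "task", id = id, kind = kind,
          optional = n$optional_step, duration = n$expected_duration,
          called_case = n$called_case
        )
        nxt <- succ(id)
        if (length(nxt) != 1L)
          sf_validation_error(sprintf("task '%s' must have exactly one outgoing flow", id))
        id <- nxt[[1]]
        next
      }
      if (kind == "sub_process") {
        n <- node_by_id[[id]]
        blocks[[length(blocks) + 1L]] <- blk(
          "subproc", id = id,
          body = blk("seq", id = paste0(id, "_body"),
                     children = parse_level_tree(n$children, n$child_flows))
        )
        id <- succ(id)[[1]]
        next
      }
      if (kind %in% c("xor_gateway", "and_gateway")) {
        outs <- succ(id)
        if (indeg(id) > 1L && length(outs) > 1L)
          sf_validation_error(sprintf(
            "gateway '%s' mixes join and split roles; model is not block-structured", id))
        if (length(outs) > 1L) {
          # split: parse every branch up to the shared join
          branches <- list(); join <- NULL
          for (o in outs) {
            br <- walk(o)
            if (is.null(br$stop))
              sf_validation_error(sprintf(
                "branch of gateway '%s' reaches an end event before its join", id))
            if (is.null(join)) join <- br$stop
            else if (!identical(join, br$stop))
              sf_validation_error(sprintf(
                "branches of gateway '%s' do not converge on a single join", id))
            branches[[length(branches) + 1L]] <-
              blk("seq", id = sprintf("%s_br%d", id, length(branches) + 1L),
                  children = br$blocks)
          }
          if (kinds[[join]] != kind)
            sf_validation_error(sprintf(
              "split '%s' (%s) joined by gateway '%s' of different kind",
              id, kind, join))
          blocks[[length(blocks) + 1L]] <- blk(
            if (kind == "xor_gateway") "xor" else "and",
            id = id, branches = branches
          )
          id <- succ(join)[[1]]
          next
        }
        # join (or degenerate pass-through gateway)
        if (indeg(id) > 1L) return(list(blocks = blocks, stop = id))
        id <- outs[[1]]
        next
      }
      if (kind == "signal_boundary_event") {
        sf_validation_error(sprintf("boundary event '%s' cannot lie on the flow path", id))
      }
      sf_validation_error(sprintf("unexpected node kind '%s' at '%s'", kind, id))
    }
  }

  res <- walk(start_id)
  if (!is.null(res$stop))
    sf_validation_error(sprintf(
      "join gateway '%s' has no matching split; model is not block-structured", res$stop))
  res$blocks
}

# Tree utilities -------------------------------------------------------------

blk_contains <- function(b, tid) {
  switch(b$type,
    task = identical(b$id, tid),
    seq = any(vapply(b$children, blk_contains, logical(1), tid = tid)),
    subproc = blk_contains(b$body, tid),
    and = ,
    xor = any(vapply(b$branches, blk_contains, logical(1), tid = tid)),
    FALSE
  )
}

blk_task_ids <- function(b) {
  switch(b$type,
    task = b$id,
    seq = unlist(lapply(b$children, blk_task_ids), use.names = FALSE),
    subproc = blk_task_ids(b$body),
    and = ,
    xor = unlist(lapply(b$branches, blk_task_ids), use.names = FALSE),
    character(0)
  )
}

# An XOR block with at least one branch that contains no tasks acts as an
# optional guard: the process may silently bypass it.
blk_is_optional_guard <- function(b) {
  b$type == "xor" &&
    any(vapply(b$branches, function(br) length(blk_task_ids(br)) == 0L, logical(1)))
}
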