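# Synthetic model families and sensor-data simulation.
#
# An intervention spec declares phases and their step blocks (linear steps,
# variable-order groups, exclusive paths, optional steps); build_models()
# renders the spec into the four deployed variants (BPMN two-granularity,
# CMMN two-granularity, structured and mixed combinations) with identical
# step-id sets, and simulate_stream() emits deterministic observation streams
# replaying a valid execution or injecting exactly one distortion class.
#
# The esophagectomy (RAMIE) family carries nine phases with instrument /
# position sensing; the cochlea-implantation (CI) family five phases with
# step-name sensing.  Phase and step content is synthetic: plausible
# placeholders, not clinically validated models.

SCENARIO_KINDS <- c("valid", "skip_required", "skip_optional", "regress",
                    "repeat", "wrong_path", "shuffled_variable",
                    "delayed_optional")

#' Declare an intervention spec
#'
#' @param name Short identifier (used as id prefix).
#' @param phases List of phases; each phase is `list(name =, blocks = list())`
#'   where a block is one of
#'   `list(type = "step", label =, optional = FALSE)`,
#'   `list(type = "variable", members = list(list(label =, optional =), ...))`,
#'   `list(type = "exclusive", branches = list(c(labels), ...))`.
#' @param sensing `"instruments_positions"` or `"step_label"`.
#' @param instruments,zones Vocabularies for rule generation.
#' @param default_duration Minutes per step.
#' @return An `intervention_spec` with deterministic step ids
#'   (`phase_01`, `step_01_02`, ...) attached.
#' @export
intervention_spec <- function(name, phases,
                              sensing = c("instruments_positions", "step_label"),
                              instruments = character(0), zones = character(0),
                              default_duration = 10) {
  sensing <- match.arg(sensing)
  compiled <- list()
  for (i in seq_along(phases)) {
    ph <- phases[[i]]
    pid <- sprintf("phase_%02d", i)
    j <- 0L
    step_id <- function() {
      j <<- j + 1L
      sprintf("step_%02d_%02d", i, j)
    }
    blocks <- list()
    for (b in ph$blocks) {
      if (b$type == "step") {
        blocks[[length(blocks) + 1L]] <- list(
          type = "step", id = step_id(), label = b$label,
          optional = isTRUE(b$optional))
      } else if (b$type == "variable") {
        if (length(b$members) < 2L)
          sf_validation_error("variable-order group needs at least 2 members")
        members <- lapply(b$members, function(m)
          list(id = step_id(), label = m$label, optional = isTRUE(m$optional)))
        blocks[[length(blocks) + 1L]] <- list(type = "variable", members = members)
      } else if (b$type == "exclusive") {
        if (length(b$branches) < 2L)
          sf_validation_error("exclusive-path group needs at least 2 branches")
        branches <- lapply(b$branches, function(br)
          lapply(br, function(lbl) list(id = step_id(), label = lbl)))
        blocks[[length(blocks) + 1L]] <- list(type = "exclusive", branches = branches)
      } else sf_validation_error(sprintf("unknown block type '%s'", b$type))
    }
    compiled[[i]] <- list(id = pid, name = ph$name, blocks = blocks)
  }
  structure(
    list(name = name, phases = compiled, sensing = sensing,
         instruments = instruments, zones = zones,
         default_duration = default_duration),
    class = "intervention_spec"
  )
}

#' Built-in intervention specs
#'
#' `ramie_spec()`: nine-phase robot-assisted minimally invasive esophagectomy
#' family with variable-order groups, optional steps and an exclusive
#' reconstruction decision; instrument/position sensing.
#' `ci_spec()`: five-phase cochlea implantation (preparation, access,
#' operation under and after the microscope, follow-up) with an exclusive
#' implant-procedure decision; step-name sensing.
#'
#' @return An [intervention_spec()].
#' @export
ramie_spec <- function() {
  s <- function(label, optional = FALSE) list(type = "step", label = label,
                                              optional = optional)
  v <- function(...) list(type = "variable", members = list(...))
  m <- function(label, optional = FALSE) list(label = label, optional = optional)
  x <- function(...) list(type = "exclusive", branches = list(...))
  intervention_spec(
    name = "ramie",
    phases = list(
      list(name = "preparation", blocks = list(
        s("patient_positioning"), s("port_placement"))),
      list(name = "abdominal_access", blocks = list(
        s("abdominal_exploration"),
        v(m("gastric_mobilization"), m("vessel_dissection"),
          m("adhesiolysis", optional = TRUE)))),
      list(name = "gastric_tube", blocks = list(
        s("gastric_tube_formation"), s("tube_inspection", optional = TRUE))),
      list(name = "abdominal_lymphadenectomy", blocks = list(
        s("celiac_lymphadenectomy"), s("hepatic_lymphadenectomy"))),
      list(name = "thoracic_access", blocks = list(
        s("repositioning"), s("thoracic_port_placement"))),
      list(name = "esophageal_dissection", blocks = list(
        v(m("esophagus_mobilization"), m("thoracic_lymphadenectomy"),
          m("pleura_inspection", optional = TRUE)))),
      list(name = "reconstruction", blocks = list(
        x(c("stomach_pullup_standard"),
          c("stomach_pullup_extended", "additional_mobilization")))),
      list(name = "anastomosis", blocks = list(
        s("anastomosis_creation"), s("leak_test"))),
      list(name = "closure", blocks = list(
        s("drain_placement", optional = TRUE), s("wound_closure")))
    ),
    sensing = "instruments_positions",
    instruments = c("grasper", "scissors", "stapler", "hook", "clip_applier",
                    "needle_holder", "suction", "retractor"),
    zones = c("abdominal_left", "abdominal_right", "thoracic_left",
              "thoracic_right", "console", "table_head", "table_side")
  )
}

#' @rdname ramie_spec
#' @export
ci_spec <- function() {
  s <- function(label, optional = FALSE) list(type = "step", label = label,
                                              optional = optional)
  v <- function(...) list(type = "variable", members = list(...))
  m <- function(label, optional = FALSE) list(label = label, optional = optional)
  x <- function(...) list(type = "exclusive", branches = list(...))
  intervention_spec(
    name = "ci",
    phases = list(
      list(name = "preparation", blocks = list(
        s("patient_preparation"), s("equipment_check"))),
      list(name = "access", blocks = list(
        s("skin_incision"), s("mastoidectomy"),
        s("facial_recess_widening", optional = TRUE))),
      list(name = "operation_under_microscope", blocks = list(
        x(c("cochleostomy", "electrode_insertion_cochleostomy"),
          c("round_window_insertion")))),
      list(name = "operation_after_microscope", blocks = list(
        v(m("implant_fixation"), m("electrode_testing"),
          m("impedance_check", optional = TRUE)))),
      list(name = "follow_up", blocks = list(
        s("wound_closure"), s("final_check")))
    ),
    sensing = "step_label"
  )
}

spec_step_table <- function(spec) {
  rows <- list()
  add <- function(id, label, phase, optional, block_type, block_key, branch = NA_integer_,
                  pos_in_branch = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      step = id, label = label, phase = phase, optional = optional,
      block_type = block_type, block = block_key, branch = branch,
      pos = pos_in_branch, stringsAsFactors = FALSE)
  }
  for (i in seq_along(spec$phases)) {
    ph <- spec$phases[[i]]
    for (k in seq_along(ph$blocks)) {
      b <- ph$blocks[[k]]
      key <- sprintf("%s_b%d", ph$id, k)
      if (b$type == "step") add(b$id, b$label, ph$id, b$optional, "step", key)
      if (b$type == "variable") for (mm in b$members)
        add(mm$id, mm$label, ph$id, mm$optional, "variable", key)
      if (b$type == "exclusive") for (br in seq_along(b$branches))
        for (p in seq_along(b$branches[[br]])) {
          st <- b$branches[[br]][[p]]
          add(st$id, st$label, ph$id, FALSE, "exclusive", key, br, p)
        }
    }
  }
  do.call(rbind, rows)
}

# BPMN rendering --------------------------------------------------------------

render_bpmn_phase <- function(ph, dur, counter) {
  nodes <- list(); flows <- list()
  gid <- function() {
    counter$g <- counter$g + 1L
    sprintf("gw_%03d", counter$g)
  }
  fid <- function() {
    counter$f <- counter$f + 1L
    sprintf("flow_%04d", counter$f)
  }
  add_node <- function(n) nodes[[length(nodes) + 1L]] <<- n
  add_flow <- function(src, tgt, label = "") {
    flows[[length(flows) + 1L]] <<- sequence_flow(fid(), src, tgt, label)
  }
  task <- function(id, label, optional = FALSE) {
    add_node(flow_node(id, "user_task", name = label, optional_step = optional,
                       expected_duration = dur))
  }
  start_id <- paste0(ph$id, "_start")
  end_id <- paste0(ph$id, "_end")
  add_node(flow_node(start_id, "start_event"))
  prev <- start_id
  for (b in ph$blocks) {
    if (b$type == "step" && !b$optional) {
      task(b$id, b$label)
      add_flow(prev, b$id)
      prev <- b$id
    } else if (b$type == "step" && b$optional) {
      g1 <- gid(); g2 <- gid()
      add_node(flow_node(g1, "xor_gateway"))
      task(b$id, b$label, optional = TRUE)
      add_node(flow_node(g2, "xor_gateway"))
      add_flow(prev, g1)
      add_flow(g1, b$id, "do")
      add_flow(b$id, g2)
      add_flow(g1, g2, "skip")
      prev <- g2
    } else if (b$type == "variable") {
      a1 <- gid(); a2 <- gid()
      add_node(flow_node(a1, "and_gateway"))
      add_node(flow_node(a2, "and_gateway"))
      add_flow(prev, a1)
      for (mm in b$members) {
        if (mm$optional) {
          x1 <- gid(); x2 <- gid()
          add_node(flow_node(x1, "xor_gateway"))
          task(mm$id, mm$label, optional = TRUE)
          add_node(flow_node(x2, "xor_gateway"))
          add_flow(a1, x1)
          add_flow(x1, mm$id, "do")
          add_flow(mm$id, x2)
          add_flow(x1, x2, "skip")
          add_flow(x2, a2)
        } else {
          task(mm$id, mm$label)
          add_flow(a1, mm$id)
          add_flow(mm$id, a2)
        }
      }
      prev <- a2
    } else if (b$type == "exclusive") {
      x1 <- gid(); x2 <- gid()
      add_node(flow_node(x1, "xor_gateway"))
      add_node(flow_node(x2, "xor_gateway"))
      add_flow(prev, x1)
      for (br in seq_along(b$branches)) {
        steps <- b$branches[[br]]
        first <- TRUE
        local_prev <- x1
        for (st in steps) {
          task(st$id, st$label)
          add_flow(local_prev, st$id,
                   if (first) sprintf("path_%d", br) else "")
          local_prev <- st$id
          first <- FALSE
        }
        add_flow(local_prev, x2)
      }
      prev <- x2
    }
  }
  add_node(flow_node(end_id, "end_event"))
  add_flow(prev, end_id)
  list(nodes = nodes, flows = flows)
}

build_bpmn <- function(spec) {
  counter <- new.env(parent = emptyenv())
  counter$g <- 0L; counter$f <- 0L
  nodes <- list(flow_node(paste0(spec$name, "_start"), "start_event"))
  flows <- list()
  fid <- function() {
    counter$f <- counter$f + 1L
    sprintf("flow_%04d", counter$f)
  }
  prev <- paste0(spec$name, "_start")
  for (ph in spec$phases) {
    body <- render_bpmn_phase(ph, spec$default_duration, counter)
    nodes[[length(nodes) + 1L]] <- flow_node(
      ph$id, "sub_process", name = ph$name,
      children = body$nodes, child_flows = body$flows)
    flows[[length(flows) + 1L]] <- sequence_flow(fid(), prev, ph$id)
    prev <- ph$id
  }
  end_id <- paste0(spec$name, "_end")
  nodes[[length(nodes) + 1L]] <- flow_node(end_id, "end_event")
  flows[[length(flows) + 1L]] <- sequence_flow(fid(), prev, end_id)
  # one exemplary foreseen event: parsed and round-tripped, no runtime role
  if (length(spec$phases) >= 2L) {
    nodes[[length(nodes) + 1L]] <- flow_node(
      paste0(spec$name, "_ev_bleeding"), "signal_boundary_event",
      name = "bleeding", attached_to = spec$phases[[2]]$id)
  }
  process_model(paste0(spec$name, "_bpmn"), name = spec$name, nodes = nodes,
                flows = flows, granularity = "two_level")
}

# CMMN rendering --------------------------------------------------------------

# items for one phase; sentries chain on the required steps of the nearest
# preceding block that has any (CMMN stays deliberately looser than BPMN:
# optional and exclusive-path items do not anchor their successors)
render_cmmn_phase_items <- function(ph, dur, extra_listener = FALSE) {
  items <- list()
  sid <- local({
    k <- 0L
    function(step) {
      k <<- k + 1L
      sprintf("sen_%s_%02d", step, k)
    }
  })
  entry_for <- function(step, anchor) {
    if (!length(anchor)) list() else list(sentry(sid(step), anchor))
  }
  anchor <- character(0)
  for (b in ph$blocks) {
    if (b$type == "step") {
      items[[length(items) + 1L]] <- plan_item(
        b$id, "human_task", name = b$label, required = !b$optional,
        manual_activation = b$optional, entry_criteria = entry_for(b$id, anchor),
        expected_duration = dur)
      if (!b$optional) anchor <- b$id
    } else if (b$type == "variable") {
      for (mm in b$members) {
        items[[length(items) + 1L]] <- plan_item(
          mm$id, "human_task", name = mm$label, required = !mm$optional,
          manual_activation = mm$optional,
          entry_criteria = entry_for(mm$id, anchor), expected_duration = dur)
      }
      anchor <- vapply(Filter(function(m) !m$optional, b$members),
                       `[[`, character(1), "id")
    } else if (b$type == "exclusive") {
      # exclusive paths rendered as optional siblings: the case model alone
      # cannot tell "exactly one path" apart from "any subset of paths"
      for (br in b$branches) {
        br_anchor <- anchor
        for (st in br) {
          items[[length(items) + 1L]] <- plan_item(
            st$id, "human_task", name = st$label, required = FALSE,
            manual_activation = TRUE,
            entry_criteria = entry_for(st$id, br_anchor),
            expected_duration = dur)
          br_anchor <- st$id
        }
      }
      # anchor unchanged: successors do not wait on optional paths
    }
  }
  if (extra_listener) {
    items[[length(items) + 1L]] <- plan_item(
      paste0(ph$id, "_ev_listener"), "event_listener", name = "bleeding",
      required = FALSE)
  }
  items
}

build_cmmn <- function(spec) {
  stages <- list()
  prev_stage <- NULL
  for (i in seq_along(spec$phases)) {
    ph <- spec$phases[[i]]
    crit <- if (is.null(prev_stage)) list() else
      list(sentry(sprintf("sen_stage_%02d", i), prev_stage))
    stages[[length(stages) + 1L]] <- plan_item(
      ph$id, "stage", name = ph$name, required = TRUE,
      entry_criteria = crit,
      children = render_cmmn_phase_items(ph, spec$default_duration,
                                         extra_listener = i == 2L))
    prev_stage <- ph$id
  }
  case_model(paste0(spec$name, "_case"), name = spec$name, plan_items = stages)
}

build_structured <- function(spec) {
  fidx <- 0L
  fid <- function() {
    fidx <<- fidx + 1L
    sprintf("flow_%04d", fidx)
  }
  nodes <- list(flow_node(paste0(spec$name, "_start"), "start_event"))
  flows <- list()
  prev <- paste0(spec$name, "_start")
  cases <- list()
  for (i in seq_along(spec$phases)) {
    ph <- spec$phases[[i]]
    cid <- sprintf("%s_%s", spec$name, ph$id)
    cases[[cid]] <- case_model(
      cid, name = ph$name,
      plan_items = render_cmmn_phase_items(ph, spec$default_duration))
    ca <- sprintf("call_%02d", i)
    nodes[[length(nodes) + 1L]] <- flow_node(ca, "call_activity",
                                             name = ph$name, called_case = cid)
    flows[[length(flows) + 1L]] <- sequence_flow(fid(), prev, ca)
    prev <- ca
  }
  end_id <- paste0(spec$name, "_end")
  nodes[[length(nodes) + 1L]] <- flow_node(end_id, "end_event")
  flows[[length(flows) + 1L]] <- sequence_flow(fid(), prev, end_id)
  root <- process_model(paste0(spec$name, "_structured_root"), name = spec$name,
                        nodes = nodes, flows = flows, granularity = "two_level")
  combination_model("structured", root, cases)
}

phase_is_variable <- function(ph) {
  any(vapply(ph$blocks, function(b)
    b$type %in% c("variable", "exclusive") ||
      (b$type == "step" && isTRUE(b$optional)), logical(1)))
}

build_mixed <- function(spec) {
  counter <- new.env(parent = emptyenv())
  counter$g <- 0L; counter$f <- 1000L  # distinct flow-id range from pure BPMN
  fid <- function() {
    counter$f <- counter$f + 1L
    sprintf("flow_%04d", counter$f)
  }
  nodes <- list(flow_node(paste0(spec$name, "_start"), "start_event"))
  flows <- list()
  prev <- paste0(spec$name, "_start")
  cases <- list()
  for (i in seq_along(spec$phases)) {
    ph <- spec$phases[[i]]
    if (phase_is_variable(ph)) {
      cid <- sprintf("%s_%s_mx", spec$name, ph$id)
      cases[[cid]] <- case_model(
        cid, name = ph$name,
        plan_items = render_cmmn_phase_items(ph, spec$default_duration))
      nid <- sprintf("call_mx_%02d", i)
      nodes[[length(nodes) + 1L]] <- flow_node(nid, "call_activity",
                                               name = ph$name, called_case = cid)
    } else {
      body <- render_bpmn_phase(ph, spec$default_duration, counter)
      nid <- ph$id
      nodes[[length(nodes) + 1L]] <- flow_node(
        nid, "sub_process", name = ph$name,
        children = body$nodes, child_flows = body$flows)
    }
    flows[[length(flows) + 1L]] <- sequence_flow(fid(), prev, nid)
    prev <- nid
  }
  end_id <- paste0(spec$name, "_end")
  nodes[[length(nodes) + 1L]] <- flow_node(end_id, "end_event")
  flows[[length(flows) + 1L]] <- sequence_flow(fid(), prev, end_id)
  root <- process_model(paste0(spec$name, "_mixed_root"), name = spec$name,
                        nodes = nodes, flows = flows, granularity = "two_level")
  combination_model("mixed", root, cases)
}

#' Build the four deployed model variants of an intervention
#'
#' Renders the spec into BPMN (two-granularity), CMMN (stage per phase),
#' a structured combination (root process of call activities, one referenced
#' case per phase) and a mixed combination (call activities only for
#' variable phases).  All variants share the same step-id set.
#'
#' @param spec An [intervention_spec()].
#' @return A `model_bundle`: list with `spec`, `steps` (step metadata table),
#'   `bpmn`, `cmmn`, `structured`, `mixed` and a `rules` slot (`NULL` until
#'   [build_rules()] fills it).
#' @export
build_models <- function(spec) {
  structure(
    list(
      spec = spec, steps = spec_step_table(spec),
      bpmn = build_bpmn(spec), cmmn = build_cmmn(spec),
      structured = build_structured(spec), mixed = build_mixed(spec),
      rules = NULL
    ),
    class = "model_bundle"
  )
}

#' Write a model bundle to disk
#'
#' Emits `<name>.bpmn`, `<name>.cmmn` and `structured/` + `mixed/`
#' combination directories under `dir`.
#'
#' @param bundle A `model_bundle`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nm <- bundle$spec$name
  write_bpmn(bundle$bpmn, file.path(dir, paste0(nm, ".bpmn")))
  write_cmmn(bundle$cmmn, file.path(dir, paste0(nm, ".cmmn")))
  write_combination(bundle$structured, file.path(dir, "structured"))
  write_combination(bundle$mixed, file.path(dir, "mixed"))
  invisible(dir)
}

#' Generate a deterministic situation-rule table
#'
#' One rule per step.  With step-name sensing, rules match the simulated step
#' label; with instrument/position sensing, each step receives an instrument
#' pair and actor positions drawn from the spec vocabularies such that
#' adjacent steps have distinguishable signatures.
#'
#' @param spec An [intervention_spec()].
#' @param seed Integer seed; identical seeds give identical rules.
#' @return List of [situation_rule()] objects.
#' @export
build_rules <- function(spec, seed = 1L) {
  steps <- spec_step_table(spec)
  if (spec$sensing == "step_label") {
    return(lapply(seq_len(nrow(steps)), function(i) situation_rule(
      sprintf("rule_%s", steps$step[i]), steps$step[i],
      label_match = steps$step[i])))
  }
  with_seed(seed, {
    instr <- sample(spec$instruments)
    zones <- sample(spec$zones)
    ni <- length(instr); nz <- length(zones)
    lapply(seq_len(nrow(steps)), function(i) {
      # cycle through shuffled vocabularies: adjacent steps always differ
      pair <- instr[c((2 * i - 2) %% ni + 1, (2 * i - 1) %% ni + 1)]
      situation_rule(
        sprintf("rule_%s", steps$step[i]), steps$step[i],
        instrument_match = sort(unique(pair)),
        position_match = list(surgeon = zones[(i - 1) %% nz + 1],
                              assistant = zones[i %% nz + 1])
      )
    })
  })
}

#' Declare a simulation scenario
#'
#' @param kind One of `r paste0('"', SCENARIO_KINDS, '"', collapse = ", ")`.
#'   `valid` replays an accepted trace; each distortion kind injects exactly
#'   one anomaly class (dropping a required or an included optional step,
#'   regressing to a completed step, repeating the current step, adding a
#'   second exclusive path, reordering a variable group, or delaying an
#'   optional step past its variable-order siblings).
#' @param seed Integer seed.
#' @return A `scenario`.
#' @export
scenario <- function(kind, seed = 1L) {
  kind <- match.arg(kind, SCENARIO_KINDS)
  structure(list(kind = kind, seed = as.integer(seed)), class = "scenario")
}

# random engine-accepted walk over the BPMN variant
walk_trace <- function(model, seed, optionals_mode = c("random", "include", "exclude"),
                       optional_ids = character(0)) {
  optionals_mode <- match.arg(optionals_mode)
  with_seed(seed, {
    inst <- start_process(model)
    repeat {
      act <- active_tasks(inst)
      act <- act[act %in% model_task_ids(model)]
      if (is_complete(inst)) {
        if (optionals_mode != "include") break
        opts <- intersect(act, optional_ids)
        if (!length(opts)) break
        act <- opts
      }
      if (!length(act)) break
      choices <- act
      if (optionals_mode == "include") {
        opts <- intersect(act, optional_ids)
        if (length(opts)) choices <- opts
      } else if (optionals_mode == "exclude") {
        rest <- setdiff(act, optional_ids)
        if (length(rest)) choices <- rest
      }
      pick <- choices[[sample.int(length(choices), 1L)]]
      inst <- complete_task(inst, pick)
    }
    inst$trace
  })
}

#' Simulate a sensor observation stream
#'
#' Deterministic for a given `(spec, scenario)` pair: the valid kind emits one
#' observation per step of an engine-accepted trace of the BPMN variant; each
#' distortion kind perturbs the valid stream in its single documented way.
#' Observation encoding follows the spec's sensing mode (instrument sets plus
#' actor positions, or plain step labels).
#'
#' @param spec An [intervention_spec()].
#' @param bundle A `model_bundle` from [build_models()].
#' @param scn A [scenario()].
#' @param rules Situation rules (defaults to `build_rules(spec, scn$seed)`);
#'   used to derive the instrument/position signature per step.
#' @return List of [sensor_observation()] objects.
#' @export
simulate_stream <- function(spec, bundle, scn, rules = NULL) {
  rules <- rules %||% build_rules(spec, scn$seed)
  steps <- bundle$steps
  optional_ids <- steps$step[steps$optional]
  model <- bundle$bpmn
  kind <- scn$kind
  mode <- switch(kind,
    skip_optional = "include",
    delayed_optional = "exclude",
    "random")
  trace <- walk_trace(model, scn$seed, mode, optional_ids)
  seq_steps <- trace

  pick1 <- function(xs, seed_off = 0L) {
    with_seed(scn$seed + seed_off, xs[[sample.int(length(xs), 1L)]])
  }

  if (kind == "skip_required") {
    # drop one step outside the first phase that is required in every
    # notation (exclusive-path members are optional on the case-model side;
    # their anomalies belong to the wrong_path kind)
    cand <- seq_steps[seq_steps %in% steps$step[!steps$optional &
                                                  steps$block_type != "exclusive" &
                                                  steps$phase != "phase_01"]]
    cand <- setdiff(cand, seq_steps[length(seq_steps)])
    drop <- pick1(cand, 1L)
    seq_steps <- seq_steps[seq_steps != drop]
  } else if (kind == "skip_optional") {
    inc <- intersect(seq_steps, optional_ids)
    if (length(inc)) seq_steps <- seq_steps[seq_steps != pick1(inc, 1L)]
  } else if (kind == "regress") {
    k <- max(2L, length(seq_steps) %/% 3L)
    seq_steps <- append(seq_steps, seq_steps[[k]], after = length(seq_steps) - 1L)
  } else if (kind == "repeat") {
    k <- with_seed(scn$seed + 1L, sample.int(length(seq_steps), 1L))
    seq_steps <- append(seq_steps, seq_steps[[k]], after = k)
  } else if (kind == "wrong_path") {
    ex <- steps[steps$block_type == "exclusive", , drop = FALSE]
    blockk <- ex$block[ex$step %in% seq_steps][1]
    taken <- ex[ex$block == blockk & ex$step %in% seq_steps, , drop = FALSE]
    other <- ex[ex$block == blockk & !(ex$branch %in% taken$branch) &
                  ex$pos == 1L, , drop = FALSE]
    intruder <- other$step[[1]]
    last_taken <- max(match(taken$step, seq_steps))
    seq_steps <- append(seq_steps, intruder, after = last_taken)
  } else if (kind == "shuffled_variable") {
    vb <- steps[steps$block_type == "variable" & !steps$optional, , drop = FALSE]
    blockk <- vb$block[[1]]
    members <- vb$step[vb$block == blockk]
    idx <- match(members, seq_steps)
    seq_steps[sort(idx)[1:2]] <- seq_steps[rev(sort(idx)[1:2])]
  } else if (kind == "delayed_optional") {
    # optional observed only after all its variable-order siblings
    vb <- steps[steps$block_type == "variable", , drop = FALSE]
    ob <- vb[vb$optional, , drop = FALSE]
    blockk <- ob$block[[1]]
    opt <- ob$step[[1]]
    siblings <- vb$step[vb$block == blockk & !vb$optional]
    last_sib <- max(match(siblings, seq_steps))
    seq_steps <- append(seq_steps, opt, after = last_sib)
  }

  dur <- spec$default_duration
  lapply(seq_along(seq_steps), function(k) {
    step <- seq_steps[[k]]
    t <- (k - 1L) * dur
    if (spec$sensing == "step_label") {
      sensor_observation(t, step_label = step)
    } else {
      r <- Find(function(x) identical(x$target_step, step), rules)
      sensor_observation(t, instruments = r$instrument_match,
                         positions = r$position_match)
    }
  })
}

#' Write / read an observation stream as line-delimited JSON
#'
#' @param stream List of [sensor_observation()] objects.
#' @param path File path.
#' @return Invisibly `path` (write) or the stream list (read).
#' @export
write_stream <- function(stream, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (obs in stream) {
    writeLines(jsonlite::toJSON(unclass(obs), auto_unbox = TRUE, na = "null",
                                digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  lapply(readLines(path), function(line) {
    x <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    sensor_observation(
      time = x$time,
      instruments = if (is.null(x$instruments)) character(0) else unlist(x$instruments),
      positions = if (is.null(x$positions)) list() else as.list(x$positions),
      step_label = if (is.null(x$step_label) || is.na(x$step_label))
        NA_character_ else x$step_label
    )
  })
}
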