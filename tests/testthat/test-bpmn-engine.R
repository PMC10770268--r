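# Token-engine semantics: activation, ordering, gateways, optional bypass.

test_that("start and completion walk a linear chain in order only", {
  m <- chain_model(3)
  inst <- start_process(m)
  expect_equal(active_tasks(inst), "step_01_01")
  expect_false(is_complete(inst))
  expect_error(complete_task(inst, "step_01_03"), class = "surgflow_out_of_order")
  inst <- complete_task(inst, "step_01_01")
  inst <- complete_task(inst, "step_01_02")
  inst <- complete_task(inst, "step_01_03")
  expect_true(is_complete(inst))
  expect_equal(active_tasks(inst), character(0))
  expect_equal(inst$trace, c("step_01_01", "step_01_02", "step_01_03"))
  expect_error(complete_task(inst, "step_01_01"), class = "surgflow_regression")
})

test_that("a parallel block activates all branches including the optional", {
  b <- variable_block_bundle(2, 1, successor = TRUE)
  inst <- start_process(b$bpmn)
  # req1, req2 and the optional opt1 all activatable; successor via lookahead
  act <- active_tasks(inst)
  expect_true(all(c("step_01_01", "step_01_02", "step_01_03") %in% act))
  inst <- complete_task(inst, "step_01_02")
  expect_true("step_01_01" %in% active_tasks(inst))
})

test_that("variable order is free, the join waits, and optionals can be skipped", {
  b <- variable_block_bundle(2, 1, successor = TRUE)
  inst <- start_process(b$bpmn)
  expect_error(complete_task(inst, "step_01_04"), class = "surgflow_out_of_order")
  inst <- complete_task(inst, "step_01_02")  # req2 first: any order
  inst <- complete_task(inst, "step_01_01")
  inst <- complete_task(inst, "step_01_04")  # successor; optional bypassed
  expect_true(is_complete(inst))
  expect_equal(task_states(inst)[["step_01_03"]], "bypassed")
  expect_false("step_01_03" %in% inst$trace)
})

test_that("engine-compatibility mode bypasses an optional once a sibling completes", {
  b <- variable_block_bundle(2, 1, successor = TRUE)
  inst <- start_process(b$bpmn, camunda_compat = TRUE)
  inst <- complete_task(inst, "step_01_01")
  expect_error(complete_task(inst, "step_01_03"),
               class = "surgflow_bypassed_task")
  # with the flag off the optional stays available until the join is passed
  inst2 <- start_process(b$bpmn, camunda_compat = FALSE)
  inst2 <- complete_task(inst2, "step_01_01")
  inst2 <- complete_task(inst2, "step_01_03")
  inst2 <- complete_task(inst2, "step_01_02")
  inst2 <- complete_task(inst2, "step_01_04")
  expect_true(is_complete(inst2))
})

test_that("completing one exclusive branch bypasses the other", {
  b <- build_models(ci_spec())
  inst <- start_process(b$bpmn)
  for (s in c("step_01_01", "step_01_02", "step_02_01", "step_02_02"))
    inst <- complete_task(inst, s)
  act <- active_tasks(inst)
  # both branch heads of the exclusive decision are activatable
  expect_true(all(c("step_03_01", "step_03_03") %in% act))
  inst <- complete_task(inst, "step_03_03")  # round-window path
  expect_equal(task_states(inst)[["step_03_01"]], "bypassed")
  expect_error(complete_task(inst, "step_03_01"), class = "surgflow_out_of_order")
})

test_that("sub-processes auto-complete and the token jumps to the next phase", {
  b <- build_models(ci_spec())
  inst <- start_process(b$bpmn)
  expect_equal(active_tasks(inst), "step_01_01")  # first task of first phase
  inst <- complete_task(inst, "step_01_01")
  inst <- complete_task(inst, "step_01_02")
  expect_equal(active_tasks(inst), "step_02_01")  # first task of next phase
})

test_that("completed tasks never un-complete and the trace only grows", {
  b <- variable_block_bundle(3, 0)
  inst <- start_process(b$bpmn)
  seen <- character(0)
  for (s in c("step_01_02", "step_01_03", "step_01_01")) {
    inst <- complete_task(inst, s)
    expect_true(all(seen %in% inst$trace))
    seen <- inst$trace
  }
  expect_equal(sort(seen), sort(c("step_01_01", "step_01_02", "step_01_03")))
})

test_that("a full valid walk over the RAMIE model reaches completion", {
  b <- build_models(ramie_spec())
  inst <- start_process(b$bpmn)
  guard <- 0L
  while (!is_complete(inst) && guard < 100L) {
    act <- intersect(active_tasks(inst), model_task_ids(b$bpmn))
    inst <- complete_task(inst, act[[1]])
    guard <- guard + 1L
  }
  expect_true(is_complete(inst))
  # every required step appears exactly once
  req <- b$steps$step[!b$steps$optional & b$steps$block_type != "exclusive"]
  expect_true(all(vapply(req, function(s) sum(inst$trace == s) == 1L, logical(1))))
})
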