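# Plan-item lifecycle semantics: activation, manual start, stage and case
# completion, and the documented flexibility of case models.

test_that("starting a case activates required items and enables optional ones", {
  b <- variable_block_bundle(2, 1)
  ci <- start_case(b$cmmn)
  expect_equal(surgflow:::item_state(ci, "step_01_01"), "active")
  expect_equal(surgflow:::item_state(ci, "step_01_02"), "active")
  expect_equal(surgflow:::item_state(ci, "step_01_03"), "enabled")
})

test_that("later-stage items stay available until the previous stage completes", {
  b <- build_models(ci_spec())
  ci <- start_case(b$cmmn)
  expect_equal(surgflow:::item_state(ci, "step_02_01"), "available")
  expect_error(complete_task(ci, "step_02_01"), class = "surgflow_lifecycle_error")
  expect_error(manually_start(ci, "step_02_01"), class = "surgflow_lifecycle_error")
})

test_that("optional items can still be started after variable siblings completed", {
  b <- variable_block_bundle(2, 1)
  ci <- start_case(b$cmmn)
  ci <- complete_task(ci, "step_01_01")
  ci <- complete_task(ci, "step_01_02")
  # in contrast to the token engine, the delayed optional is still possible
  ci <- manually_start(ci, "step_01_03")
  ci <- complete_task(ci, "step_01_03")
  expect_equal(ci$trace, c("step_01_01", "step_01_02", "step_01_03"))
})

test_that("exclusive paths modeled as optional siblings can all be executed", {
  b <- build_models(ci_spec())
  ci <- start_case(b$cmmn)
  for (s in c("step_01_01", "step_01_02", "step_02_01", "step_02_02"))
    ci <- complete_task(ci, s)
  ci <- complete_stage(ci, "phase_02")
  # both exclusive branch heads are enabled; both can be run (known limit)
  ci <- manually_start(ci, "step_03_01")
  ci <- complete_task(ci, "step_03_01")
  ci <- manually_start(ci, "step_03_03")
  ci <- complete_task(ci, "step_03_03")
  expect_true(all(c("step_03_01", "step_03_03") %in% ci$trace))
})

test_that("stages with optional children need manual completion, which disables them", {
  b <- build_models(ci_spec())
  ci <- start_case(b$cmmn)
  ci <- complete_task(ci, "step_01_01")
  ci <- complete_task(ci, "step_01_02")
  # phase 1 has only required children: auto-completed, explicit call a no-op
  expect_equal(surgflow:::item_state(ci, "phase_01"), "completed")
  expect_identical(complete_stage(ci, "phase_01")$item_states,
                   ci$item_states)
  ci <- complete_task(ci, "step_02_01")
  expect_error(complete_stage(ci, "phase_02"), class = "surgflow_stage_incomplete")
  ci <- complete_task(ci, "step_02_02")
  expect_equal(surgflow:::item_state(ci, "phase_02"), "active")
  ci <- complete_stage(ci, "phase_02")
  expect_equal(surgflow:::item_state(ci, "step_02_03"), "disabled")
  expect_error(manually_start(ci, "step_02_03"), class = "surgflow_lifecycle_error")
  # next stage activated automatically by the completion of the one before
  expect_equal(surgflow:::item_state(ci, "phase_03"), "active")
})

test_that("a stage with an active child refuses completion", {
  b <- variable_block_bundle(2, 1)
  ci <- start_case(b$cmmn)
  ci <- complete_task(ci, "step_01_01")
  ci <- complete_task(ci, "step_01_02")
  ci <- manually_start(ci, "step_01_03")
  expect_error(complete_stage(ci, "phase_01"), class = "surgflow_stage_busy")
})

test_that("the case completes and closes manually after the last task, then is immutable", {
  b <- variable_block_bundle(2, 0)
  ci <- start_case(b$cmmn)
  expect_error(complete_case(ci), class = "surgflow_case_incomplete")
  ci <- complete_task(ci, "step_01_01")
  ci <- complete_task(ci, "step_01_02")
  ci <- complete_case(ci)
  expect_equal(ci$case_state, "completed")
  ci <- close_case(ci)
  expect_equal(ci$case_state, "closed")
  expect_error(complete_case(ci), class = "surgflow_immutable_case")
})

test_that("lifecycle transitions follow available -> enabled/active -> completed", {
  # property-style: random transition sequences on the CI case never reach an
  # illegal state, and every refusal is a classed lifecycle condition
  b <- build_models(ci_spec())
  # never-activated items may be disabled when their stage closes
  legal_next <- list(available = c("enabled", "active", "disabled"),
                     enabled = c("active", "disabled"),
                     active = c("completed"),
                     completed = character(0), disabled = character(0))
  set.seed(42)
  n_transitions <- 0L
  for (rep in 1:8) {
    ci <- start_case(b$cmmn)
    prev <- ci$item_states
    for (step in 1:40) {
      live <- names(ci$item_states)[ci$item_states %in% c("active", "enabled")]
      t <- if (length(live) && runif(1) < 0.7) sample(live, 1)
           else sample(names(ci$index), 1)
      op <- sample(c("complete", "start", "stage"), 1)
      ci2 <- tryCatch(switch(op,
        complete = complete_task(ci, t),
        start = manually_start(ci, t),
        stage = complete_stage(ci, t)
      ), surgflow_error = function(e) NULL)
      if (is.null(ci2)) next
      cur <- ci2$item_states
      changed <- names(cur)[cur != prev]
      for (id in changed) {
        n_transitions <- n_transitions + 1L
        expect_true(cur[[id]] %in% legal_next[[prev[[id]]]],
                    info = sprintf("%s: %s -> %s", id, prev[[id]], cur[[id]]))
      }
      ci <- ci2
      prev <- cur
    }
  }
  expect_gt(n_transitions, 50)  # the walk really exercised the lifecycle
})

test_that("required items are never disabled", {
  b <- build_models(ci_spec())
  ci <- start_case(b$cmmn)
  for (s in c("step_01_01", "step_01_02", "step_02_01", "step_02_02"))
    ci <- complete_task(ci, s)
  ci <- complete_stage(ci, "phase_02")
  req <- names(ci$index)[vapply(ci$index, function(e)
    e$item$required && e$item$kind == "human_task", logical(1))]
  expect_false(any(ci$item_states[req] == "disabled"))
})
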