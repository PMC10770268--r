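# Controller semantics and end-to-end sessions.

test_that("recognizing the successor completes the running task", {
  m <- chain_model(3)
  inst <- start_process(m)
  res <- step_controller(inst, "step_01_01", NA_character_)
  expect_true(res$ok)
  expect_length(res$actions, 0)  # first situation: already active
  res2 <- step_controller(res$runtime, "step_01_02", "step_01_01")
  expect_true(res2$ok)
  kinds <- vapply(res2$actions, `[[`, character(1), "kind")
  els <- vapply(res2$actions, `[[`, character(1), "element")
  expect_equal(kinds, "complete_task")
  expect_equal(els, "step_01_01")
})

test_that("repetition of the current situation is a no-op", {
  m <- chain_model(2)
  inst <- start_process(m)
  res <- step_controller(inst, "step_01_01", "step_01_01")
  expect_true(res$ok)
  expect_equal(res$actions[[1]]$kind, "none")
  expect_equal(res$actions[[1]]$reason, "repetition")
})

test_that("a refused observation leaves the runtime untouched", {
  m <- chain_model(3)
  inst <- start_process(m)
  res <- step_controller(inst, "step_01_03", "step_01_01")  # skips step 2
  expect_false(res$ok)
  # original instance unchanged: step 1 still activatable, empty trace
  expect_equal(active_tasks(inst), "step_01_01")
  expect_length(inst$trace, 0)
})

test_that("an enabled optional item is manually started before activation", {
  b <- variable_block_bundle(2, 1)
  ci <- start_case(b$cmmn)
  res <- step_controller(ci, "step_01_03", NA_character_)
  expect_true(res$ok)
  kinds <- vapply(res$actions, `[[`, character(1), "kind")
  expect_true("manual_start" %in% kinds)
})

test_that("moving to the next phase completes a stage blocked by an un-run optional", {
  b <- build_models(ci_spec())
  ci <- start_case(b$cmmn)
  ci <- complete_task(ci, "step_01_01")
  ci <- complete_task(ci, "step_01_02")
  ci <- complete_task(ci, "step_02_01")
  # current situation: step_02_02; recognized: first task of phase 3
  res <- step_controller(ci, "step_03_03", "step_02_02")
  expect_true(res$ok)
  kinds <- vapply(res$actions, `[[`, character(1), "kind")
  expect_equal(kinds, c("complete_task", "complete_stage", "manual_start"))
  expect_equal(surgflow:::item_state(res$runtime, "step_02_03"), "disabled")
})

test_that("structured-combination sessions add case changes around stage content", {
  spec <- ci_spec()
  b <- build_models(spec)
  rules <- build_rules(spec, 5)
  stream <- simulate_stream(spec, b, scenario("valid", 5), rules)
  r_cmmn <- run_session(b, stream, rules, variant = "cmmn")
  r_comb <- run_session(b, stream, rules, variant = "structured")
  expect_true(r_comb$completed)
  expect_equal(r_comb$trace, r_cmmn$trace)
  kinds <- vapply(r_comb$actions, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "enter_call_activity"), 5)
  expect_equal(sum(kinds == "close_case"), 5)
  expect_false(any(vapply(r_cmmn$actions, `[[`, character(1), "kind") ==
                     "enter_call_activity"))
})

test_that("valid streams complete without refusals on every variant", {
  for (spec in list(ci_spec(), ramie_spec())) {
    b <- build_models(spec)
    rules <- build_rules(spec, 2)
    stream <- simulate_stream(spec, b, scenario("valid", 2), rules)
    for (v in c("bpmn", "cmmn", "structured", "mixed")) {
      r <- run_session(b, stream, rules, variant = v)
      expect_true(r$completed, info = paste(spec$name, v))
      expect_equal(r$refusals, 0, info = paste(spec$name, v))
    }
  }
})

test_that("skipping a required step leaves the session incomplete with refusals", {
  spec <- ramie_spec()
  b <- build_models(spec)
  rules <- build_rules(spec, 2)
  stream <- simulate_stream(spec, b, scenario("skip_required", 2), rules)
  r <- run_session(b, stream, rules, variant = "bpmn")
  expect_false(r$completed)
  expect_gt(r$refusals, 0)
})

test_that("delayed optionals and second exclusive paths split BPMN from CMMN", {
  for (kind in c("delayed_optional", "wrong_path")) {
    for (spec in list(ci_spec(), ramie_spec())) {
      b <- build_models(spec)
      rules <- build_rules(spec, 4)
      stream <- simulate_stream(spec, b, scenario(kind, 4), rules)
      r_b <- run_session(b, stream, rules, variant = "bpmn")
      r_c <- run_session(b, stream, rules, variant = "cmmn")
      expect_gt(r_b$refusals, 0, label = paste(kind, spec$name, "bpmn refusals"))
      expect_equal(r_c$refusals, 0, info = paste(kind, spec$name, "cmmn"))
      expect_true(r_c$completed, info = paste(kind, spec$name, "cmmn"))
    }
  }
})

test_that("session reports serialize as line-delimited records", {
  spec <- ci_spec()
  b <- build_models(spec)
  stream <- simulate_stream(spec, b, scenario("valid", 1))
  r <- run_session(b, stream, build_rules(spec, 1), variant = "bpmn")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_session_report(r, path)
  lines <- readLines(path)
  expect_length(lines, nrow(r$rows) + 1)  # one per observation plus summary
  summary <- jsonlite::fromJSON(lines[[length(lines)]])
  expect_true(summary$completed)
})
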