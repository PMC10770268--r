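# Process-knowledge extraction: next steps, completable instances,
# remaining duration.

test_that("static lookahead fans out over gateways and crosses phase boundaries", {
  b <- build_models(ci_spec())
  # last preparation task -> first access task (through sub-process borders)
  expect_equal(static_next_steps(b$bpmn, "step_01_02"), "step_02_01")
  # before an optional step and the phase border: the optional task, and via
  # its bypass the first task of every branch of the next decision
  expect_setequal(static_next_steps(b$bpmn, "step_02_02"),
                  c("step_02_03", "step_03_01", "step_03_03"))
  # sentinel start
  expect_equal(static_next_steps(b$bpmn, "start"), "step_01_01")
  expect_error(static_next_steps(b$bpmn, "ghost"), class = "surgflow_lookup_error")
})

test_that("a task before a parallel block sees the first task of every branch", {
  b <- variable_block_bundle(2, 1, successor = TRUE)
  spec2 <- intervention_spec("pre", list(list(name = "p", blocks = list(
    list(type = "step", label = "before"),
    list(type = "variable", members = list(
      list(label = "a", optional = FALSE), list(label = "b", optional = FALSE)))))))
  m <- build_models(spec2)$bpmn
  expect_setequal(static_next_steps(m, "step_01_01"),
                  c("step_01_02", "step_01_03"))
})

test_that("last task before the end event has no next steps", {
  m <- chain_model(2)
  expect_equal(static_next_steps(m, "step_01_02"), character(0))
})

test_that("dynamic next steps equal the engine's activatable set on replay", {
  b <- build_models(ci_spec())
  ts <- enumerate_traces(b$bpmn, camunda_compat = TRUE)
  for (tr in ts$traces[seq_len(min(10, length(ts$traces)))]) {
    for (k in 0:length(tr)) {
      prefix <- tr[seq_len(k)]
      inst <- surgflow:::replay_trace(b$bpmn, prefix)
      expect_equal(dynamic_next_steps(b$bpmn, prefix), active_tasks(inst))
    }
  }
  expect_error(dynamic_next_steps(b$bpmn, c("step_05_01")),
               class = "surgflow_replay_error")
})

test_that("completable instances and reasonableness follow the lookahead", {
  m <- chain_model(3)
  pk <- completable_instances(m, character(0), "step_01_02",
                              running = "step_01_01")
  expect_equal(pk$completable, "step_01_01")
  expect_false(pk$reasonable)  # two-steps-ahead is not activatable yet
  pk2 <- completable_instances(m, "step_01_01", "step_01_02",
                               running = "step_01_02")
  expect_true(pk2$reasonable)
  # repetition of the last completed step counts as reasonable
  pk3 <- completable_instances(m, "step_01_01", "step_01_01",
                               running = "step_01_02")
  expect_true(pk3$reasonable)
  expect_equal(pk3$completable, character(0))
  # unreachable candidate: not reasonable, nothing completable
  pk4 <- completable_instances(m, character(0), "ghost", running = "step_01_01")
  expect_false(pk4$reasonable)
  expect_equal(pk4$completable, character(0))
})

test_that("remaining duration is additive over required steps and reports delay", {
  m <- chain_model(3)  # 3 steps of 10 min
  est <- remaining_duration(m, "step_01_01", clock = 12)
  expect_true(est$available)
  expect_equal(est$rsd, 20)
  expect_equal(est$delay, 2)
  est0 <- remaining_duration(m, character(0), clock = 0)
  expect_equal(est0$rsd, 30)
  expect_equal(est0$delay, 0)
})

test_that("optional steps are excluded and exclusive branches contribute the maximum", {
  b <- build_models(ci_spec())
  est <- remaining_duration(b$bpmn, character(0), clock = 0)
  # 8 required linear/variable steps + max(2, 1) exclusive branch steps
  expect_equal(est$rsd, (8 + 2) * 10)
  # after resolving the decision toward the short branch the remainder drops
  prefix <- c("step_01_01", "step_01_02", "step_02_01", "step_02_02", "step_03_03")
  est2 <- remaining_duration(b$bpmn, prefix, clock = 50)
  expect_equal(est2$rsd, 4 * 10)  # step_04_01/02 + step_05_01/02
  expect_equal(est2$delay, 0)
})

test_that("rsd decreases monotonically along a valid trace", {
  b <- build_models(ramie_spec())
  tr <- surgflow:::walk_trace(b$bpmn, 7)
  last <- Inf
  for (k in 0:length(tr)) {
    est <- remaining_duration(b$bpmn, tr[seq_len(k)], clock = 0)
    expect_lte(est$rsd, last)
    last <- est$rsd
  }
  expect_equal(last, 0)
})

test_that("missing durations give an unavailable estimate, not an error", {
  m <- process_model("nd", nodes = list(
    flow_node("s", "start_event"), flow_node("a", "user_task"),
    flow_node("e", "end_event")
  ), flows = list(sequence_flow("f1", "s", "a"), sequence_flow("f2", "a", "e")))
  est <- remaining_duration(m)
  expect_false(est$available)
  expect_true(is.na(est$rsd))
})
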