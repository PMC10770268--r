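# Reading, validating and writing the BPMN / CMMN subsets.

test_that("a minimal start-task-end chain parses to a 3-node model with 2 flows", {
  path <- withr::local_tempfile(fileext = ".bpmn")
  m <- process_model("mini", nodes = list(
    flow_node("s", "start_event"),
    flow_node("a", "user_task", name = "only step"),
    flow_node("e", "end_event")
  ), flows = list(sequence_flow("f1", "s", "a"), sequence_flow("f2", "a", "e")))
  write_bpmn(m, path)
  m2 <- read_bpmn(path)
  expect_length(m2$nodes, 3)
  expect_length(m2$flows, 2)
  expect_equal(model_task_ids(m2), "a")
})

test_that("generated fixtures round-trip structurally through BPMN and CMMN XML", {
  for (spec in list(ci_spec(), ramie_spec())) {
    b <- build_models(spec)
    fb <- withr::local_tempfile(fileext = ".bpmn")
    write_bpmn(b$bpmn, fb)
    expect_equal(read_bpmn(fb), b$bpmn)
    fc <- withr::local_tempfile(fileext = ".cmmn")
    write_cmmn(b$cmmn, fc)
    expect_equal(read_cmmn(fc), b$cmmn)
  }
})

test_that("combination bundles round-trip including call-activity references", {
  b <- build_models(ramie_spec())
  dir <- withr::local_tempdir()
  write_combination(b$structured, dir)
  back <- read_combination(dir)
  expect_equal(back$style, "structured")
  expect_equal(back$root, b$structured$root)
  expect_setequal(names(back$cases), names(b$structured$cases))
  calls <- Filter(function(n) n$kind == "call_activity", back$root$nodes)
  expect_true(all(vapply(calls, `[[`, character(1), "called_case") %in%
                    names(back$cases)))
})

test_that("an empty-name task serializes and round-trips", {
  path <- withr::local_tempfile(fileext = ".bpmn")
  m <- process_model("empty", nodes = list(
    flow_node("s", "start_event"), flow_node("a", "user_task", name = ""),
    flow_node("e", "end_event")
  ), flows = list(sequence_flow("f1", "s", "a"), sequence_flow("f2", "a", "e")))
  write_bpmn(m, path)
  expect_equal(read_bpmn(path)$nodes[["a"]]$name, "")
})

test_that("dangling flow references and duplicate ids are validation errors", {
  expect_error(
    process_model("bad", nodes = list(
      flow_node("s", "start_event"), flow_node("a", "user_task"),
      flow_node("e", "end_event")
    ), flows = list(sequence_flow("f1", "s", "nope"),
                    sequence_flow("f2", "a", "e"))),
    class = "surgflow_validation_error"
  )
  expect_error(
    process_model("dup", nodes = list(
      flow_node("s", "start_event"), flow_node("a", "user_task"),
      flow_node("a", "user_task"), flow_node("e", "end_event")
    ), flows = list()),
    class = "surgflow_validation_error"
  )
})

test_that("elements outside the supported subset are rejected by name, not dropped", {
  path <- withr::local_tempfile(fileext = ".bpmn")
  writeLines(sprintf('<definitions xmlns="%s" id="d" targetNamespace="x">
    <process id="p"><startEvent id="s"/>
    <scriptTask id="bad"/>
    <endEvent id="e"/>
    <sequenceFlow id="f1" sourceRef="s" targetRef="bad"/>
    <sequenceFlow id="f2" sourceRef="bad" targetRef="e"/>
    </process></definitions>', surgflow:::BPMN_NS), path)
  err <- expect_error(read_bpmn(path), class = "surgflow_unsupported_element")
  expect_true("scriptTask" %in% err$elements)
})

test_that("malformed XML fails with a parse error", {
  path <- withr::local_tempfile(fileext = ".bpmn")
  writeLines("<definitions><unclosed>", path)
  expect_error(read_bpmn(path), class = "surgflow_parse_error")
})

test_that("CMMN sentries citing unknown items and non-constant rules are rejected", {
  expect_error(
    case_model("c", plan_items = list(
      plan_item("a", "human_task",
                entry_criteria = list(sentry("s1", "ghost")))
    )),
    class = "surgflow_validation_error"
  )
  path <- withr::local_tempfile(fileext = ".cmmn")
  writeLines(sprintf('<definitions xmlns="%s" id="d" targetNamespace="x">
    <case id="c"><casePlanModel id="cp">
      <planItem id="a" definitionRef="def_a">
        <itemControl><requiredRule id="r"><condition>${x > 1}</condition></requiredRule></itemControl>
      </planItem>
      <humanTask id="def_a"/>
    </casePlanModel></case></definitions>', surgflow:::CMMN_NS), path)
  expect_error(read_cmmn(path), class = "surgflow_unsupported_rule")
})

test_that("optional plan items carry the manual-activation convention after parsing", {
  for (spec in list(ci_spec(), ramie_spec())) {
    b <- build_models(spec)
    fc <- withr::local_tempfile(fileext = ".cmmn")
    write_cmmn(b$cmmn, fc)
    items <- surgflow:::flatten_items(read_cmmn(fc)$plan_items)
    for (it in items) {
      if (it$kind == "human_task" && !it$required)
        expect_true(it$manual_activation, info = it$item_id)
    }
  }
})

test_that("CMMN task set equals the BPMN user-task set of the same intervention", {
  for (spec in list(ci_spec(), ramie_spec())) {
    b <- build_models(spec)
    expect_setequal(case_task_ids(b$cmmn), model_task_ids(b$bpmn))
  }
})
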