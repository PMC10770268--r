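# Trace enumeration: closed forms, engine equivalence, superset property.

test_that("a chain of three required tasks accepts exactly one trace", {
  ts <- enumerate_traces(chain_model(3))
  expect_length(ts$traces, 1)
  expect_equal(ts$traces[[1]], c("step_01_01", "step_01_02", "step_01_03"))
})

test_that("variable blocks match the closed form for k+m <= 5", {
  for (k in 1:3) for (m in 0:2) {
    if (k + m > 5 || k + m < 2) next
    b <- variable_block_bundle(k, m)
    n <- length(enumerate_traces(b$bpmn, camunda_compat = FALSE)$traces)
    expect_equal(n, variable_block_trace_count(k, m), info = sprintf("k=%d m=%d", k, m))
    # case-model semantics accept the same count for a single stage
    nc <- length(enumerate_traces(b$cmmn)$traces)
    expect_equal(nc, variable_block_trace_count(k, m), info = sprintf("cmmn k=%d m=%d", k, m))
  }
})

test_that("five variable-order tasks with one optional yield 144 paths", {
  b <- variable_block_bundle(4, 1)
  expect_equal(count_traces(b$bpmn), 144)
  expect_equal(variable_block_trace_count(4, 1), 144)
})

test_that("engine-accepted trace sets equal the oracle on fixture fragments", {
  fragments <- list(
    variable_block_bundle(2, 1, successor = TRUE),
    variable_block_bundle(3, 1),
    build_models(intervention_spec("frag", list(
      list(name = "p1", blocks = list(
        list(type = "step", label = "pre"),
        list(type = "exclusive", branches = list(c("x1", "x2"), c("y1"))))),
      list(name = "p2", blocks = list(
        list(type = "step", label = "post", optional = TRUE),
        list(type = "step", label = "last")))
    )))
  )
  for (b in fragments) {
    for (compat in c(FALSE, TRUE)) {
      oracle <- trace_keys(enumerate_traces(b$bpmn, camunda_compat = compat))
      engine <- trace_keys(surgflow:::engine_trace_set(b$bpmn, camunda_compat = compat))
      expect_equal(engine, oracle, info = paste(b$spec$name, "compat", compat))
    }
    oracle_c <- trace_keys(enumerate_traces(b$cmmn))
    engine_c <- trace_keys(surgflow:::engine_trace_set(b$cmmn))
    expect_equal(engine_c, oracle_c, info = paste(b$spec$name, "cmmn"))
  }
})

test_that("case-model trace sets are a superset of the token-engine sets", {
  b <- variable_block_bundle(2, 1, successor = TRUE)
  bp <- trace_keys(enumerate_traces(b$bpmn, camunda_compat = TRUE))
  cm <- trace_keys(enumerate_traces(b$cmmn))
  expect_true(all(bp %in% cm))
  # every extra case-model trace delays the optional past a sibling
  extras <- setdiff(cm, bp)
  expect_gt(length(extras), 0)
  opt <- "step_01_03"
  sibs <- c("step_01_01", "step_01_02")
  for (key in extras) {
    tr <- strsplit(key, " ", fixed = TRUE)[[1]]
    p <- match(opt, tr)
    expect_false(is.na(p), info = key)
    expect_true(any(match(sibs, tr) < p), info = key)
  }
})

test_that("exclusive-path fragments diverge only by the number of branches taken", {
  b <- build_models(intervention_spec("ex", list(list(name = "p", blocks = list(
    list(type = "step", label = "pre"),
    list(type = "exclusive", branches = list(c("x1"), c("y1"))),
    list(type = "step", label = "post"))))))
  bp <- trace_keys(enumerate_traces(b$bpmn, camunda_compat = TRUE))
  cm <- trace_keys(enumerate_traces(b$cmmn))
  expect_true(all(bp %in% cm))
  branch_heads <- c("step_01_02", "step_01_03")
  for (key in bp) {
    tr <- strsplit(key, " ", fixed = TRUE)[[1]]
    expect_equal(sum(branch_heads %in% tr), 1)  # exactly one path on the token engine
  }
  # every case-only trace relaxes the exclusive decision: not exactly one
  # branch, or a branch task delayed past the block's successor
  for (key in setdiff(cm, bp)) {
    tr <- strsplit(key, " ", fixed = TRUE)[[1]]
    n_heads <- sum(branch_heads %in% tr)
    heads_pos <- match(branch_heads, tr)
    delayed <- any(heads_pos > match("step_01_04", tr), na.rm = TRUE)
    expect_true(n_heads != 1 || delayed, info = key)
  }
})

test_that("the enumeration cap sets the truncated flag", {
  b <- variable_block_bundle(4, 1)
  ts <- enumerate_traces(b$bpmn, limit = 10)
  expect_true(ts$truncated)
  expect_length(ts$traces, 10)
})

test_that("required-task conservation holds for every enumerated trace", {
  b <- build_models(intervention_spec("frag", list(
    list(name = "p1", blocks = list(
      list(type = "variable", members = list(
        list(label = "a", optional = FALSE), list(label = "b", optional = FALSE),
        list(label = "c", optional = TRUE))),
      list(type = "step", label = "d"))))))
  req <- c("step_01_01", "step_01_02", "step_01_04")
  for (model in list(b$bpmn, b$cmmn)) {
    ts <- enumerate_traces(model)
    for (tr in ts$traces) {
      expect_true(all(vapply(req, function(s) sum(tr == s) == 1L, logical(1))))
    }
  }
})
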