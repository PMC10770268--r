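# Sensor scoring and knowledge fusion.

test_that("a step-label observation scores its named step 1.0", {
  rules <- build_rules(ci_spec(), 1)
  obs <- sensor_observation(0, step_label = "step_02_01")
  s <- score_sensors(obs, rules)
  expect_equal(s, c(step_02_01 = 1))
})

test_that("two equal-scoring rules give a uniform distribution; unknown input none", {
  rules <- list(
    situation_rule("r1", "a", instrument_match = "hook"),
    situation_rule("r2", "b", instrument_match = "hook")
  )
  obs <- sensor_observation(0, instruments = "hook")
  expect_equal(score_sensors(obs, rules), c(a = 0.5, b = 0.5))
  none <- score_sensors(sensor_observation(0, instruments = "unseen"), rules)
  expect_length(none, 0)
})

test_that("instrument subsets and positions must both match for a rule to fire", {
  r <- situation_rule("r", "a", instrument_match = c("hook", "grasper"),
                      position_match = list(surgeon = "console"))
  hit <- sensor_observation(0, instruments = c("hook", "grasper", "suction"),
                            positions = list(surgeon = "console"))
  miss_pos <- sensor_observation(0, instruments = c("hook", "grasper"),
                                 positions = list(surgeon = "table_head"))
  miss_instr <- sensor_observation(0, instruments = "hook",
                                   positions = list(surgeon = "console"))
  expect_equal(score_sensors(hit, list(r)), c(a = 1))
  expect_length(score_sensors(miss_pos, list(r)), 0)
  expect_length(score_sensors(miss_instr, list(r)), 0)
})

test_that("fusion follows the convex combination with a uniform process prior", {
  sk <- fuse(c(s1 = 0.6, s2 = 0.4), list(next_steps = "s2", reasonable = TRUE),
             impact_config(0.8))
  expect_equal(unname(sk$candidates["s1"]), 0.48)
  expect_equal(unname(sk$candidates["s2"]), 0.52)
  expect_equal(sk$best, "s2")
})

test_that("extreme weights reproduce the sensor ranking and the process prior", {
  p <- c(s1 = 0.7, s2 = 0.3)
  pk <- list(next_steps = c("s2", "s3"), reasonable = TRUE)
  sk1 <- fuse(p, pk, impact_config(1.0))
  expect_equal(sk1$candidates[c("s1", "s2")], p)
  expect_equal(sk1$best, "s1")
  sk0 <- fuse(p, pk, impact_config(0.0))
  expect_equal(unname(sk0$candidates["s2"]), 0.5)
  expect_equal(unname(sk0$candidates["s3"]), 0.5)
  expect_equal(unname(sk0$candidates["s1"]), 0)
  expect_equal(sk0$best, "s2")  # lexical tie-break
})

test_that("empty sensor evidence falls back to a uniform process prior", {
  sk <- fuse(stats::setNames(numeric(0), character(0)),
             list(next_steps = c("a", "b"), reasonable = TRUE), impact_config(0.8))
  expect_equal(unname(sk$candidates), c(0.5, 0.5))
  expect_equal(names(sk$candidates), c("a", "b"))
})

test_that("no evidence at all yields a no-recognition result", {
  sk <- fuse(stats::setNames(numeric(0), character(0)),
             list(next_steps = character(0), reasonable = FALSE), impact_config())
  expect_true(is.na(sk$best))
  expect_false(sk$reasonable)
})

test_that("normalization and impact monotonicity hold over random inputs", {
  set.seed(7)
  steps <- paste0("s", 1:6)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    p <- stats::setNames(runif(k), sample(steps, k))
    p <- p / sum(p)
    nxt <- sample(steps, sample(1:3, 1))
    w1 <- runif(1); w2 <- runif(1, 0, w1)  # w2 has larger process weight
    f1 <- fuse(p, list(next_steps = nxt, reasonable = TRUE), impact_config(w1))
    f2 <- fuse(p, list(next_steps = nxt, reasonable = TRUE), impact_config(w2))
    expect_equal(sum(f1$candidates), 1)
    expect_equal(sum(f2$candidates), 1)
    inside <- intersect(names(f1$candidates), nxt)
    outside <- setdiff(intersect(names(f1$candidates), names(p)), nxt)
    # raising the process weight never lowers an inside step's score relative
    # to an outside one (score ratio is monotone in the process weight)
    for (a in inside) for (b in outside) {
      r1 <- f1$candidates[[a]] / f1$candidates[[b]]
      r2 <- f2$candidates[[a]] / f2$candidates[[b]]
      expect_gte(round(r2 - r1, 9), 0)
    }
  }
})

test_that("recognition on a valid stream always names the simulated step", {
  spec <- ci_spec()
  b <- build_models(spec)
  rules <- build_rules(spec, 3)
  stream <- simulate_stream(spec, b, scenario("valid", 3), rules)
  labels <- vapply(stream, `[[`, character(1), "step_label")
  trace <- character(0)
  current <- NULL
  for (i in seq_along(stream)) {
    sk <- recognize(stream[[i]], b$bpmn, trace, rules, impact_config(),
                    current = current)
    expect_equal(sk$best, labels[[i]])
    expect_true(sk$reasonable)
    if (!is.null(current)) trace <- c(trace, current)
    current <- sk$best
  }
})

test_that("a downstream step in a distorted stream is flagged unreasonable", {
  spec <- ci_spec()
  b <- build_models(spec)
  rules <- build_rules(spec, 1)
  obs <- sensor_observation(0, step_label = "step_04_01")
  sk <- recognize(obs, b$bpmn, trace = character(0), rules, impact_config(),
                  current = "step_01_01")
  expect_equal(sk$best, "step_04_01")
  expect_false(sk$reasonable)
})

test_that("phase-level recognition is the phase containing the best step", {
  spec <- ci_spec()
  b <- build_models(spec)
  rules <- build_rules(spec, 1)
  sk <- recognize(sensor_observation(0, step_label = "step_01_01"),
                  b$bpmn, character(0), rules)
  expect_equal(sk$phase, "phase_01")
})
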