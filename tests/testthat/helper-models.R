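# Shared fixture builders: all models are generated in code at test time.

# single-phase model family with one variable-order block of k required and
# m optional tasks (optionally followed by a successor step)
variable_block_bundle <- function(k, m, successor = FALSE) {
  members <- c(
    lapply(seq_len(k), function(i) list(label = paste0("req", i), optional = FALSE)),
    if (m > 0) lapply(seq_len(m), function(i)
      list(label = paste0("opt", i), optional = TRUE))
  )
  blocks <- list(list(type = "variable", members = members))
  if (successor) blocks <- c(blocks, list(list(type = "step", label = "after")))
  build_models(intervention_spec("blk", list(list(name = "p", blocks = blocks))))
}

# minimal linear chain of n required steps
chain_model <- function(n = 3) {
  blocks <- lapply(seq_len(n), function(i) list(type = "step", label = paste0("t", i)))
  build_models(intervention_spec("chain", list(list(name = "p", blocks = blocks))))$bpmn
}

trace_keys <- function(ts) sort(vapply(ts$traces, paste, character(1), collapse = " "))

expect_refused <- function(expr, class = "surgflow_error") {
  expect_error(expr, class = class)
}

# step labels of an observation stream (works for both sensing modes)
stream_steps <- function(stream, rules) {
  vapply(stream, function(o) {
    if (!is.na(o$step_label)) return(o$step_label)
    r <- Find(function(x) setequal(x$instrument_match, o$instruments) &&
                identical(x$position_match[order(names(x$position_match))],
                          o$positions[order(names(o$positions))]), rules)
    r$target_step
  }, character(1))
}
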