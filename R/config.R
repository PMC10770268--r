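# Declarative session configuration: impact weights, engine compatibility
# flags and the seed, serialized as YAML.

#' Default session configuration
#'
#' @param sensor_weight Sensor-knowledge impact fraction (default 0.8; process
#'   knowledge gets the complementary 0.2).
#' @param camunda_compat BPMN engine-compatibility flag, see [start_process()].
#' @param knowledge_source `"bpmn"` to always derive process knowledge from
#'   the structured BPMN variant of the intervention (the default, reflecting
#'   that the structured model stands in for knowledge from similar executed
#'   cases), or `"native"` to use the controlled model itself where possible.
#' @param first_stage_exception Logical; when `TRUE`, candidates inside the
#'   first stage of a case bypass the reasonableness veto in reporting.
#' @param seed Integer seed for stream and rule generation.
#' @return A `session_config` list.
#' @export
session_config <- function(sensor_weight = 0.8, camunda_compat = TRUE,
                           knowledge_source = c("bpmn", "native"),
                           first_stage_exception = TRUE, seed = 1L) {
  structure(
    list(
      sensor_weight = as.numeric(sensor_weight),
      camunda_compat = isTRUE(camunda_compat),
      knowledge_source = match.arg(knowledge_source),
      first_stage_exception = isTRUE(first_stage_exception),
      seed = as.integer(seed)
    ),
    class = "session_config"
  )
}

#' Read / write a session configuration file (YAML)
#'
#' Missing fields fall back to the defaults of [session_config()].
#'
#' @param path YAML file path.
#' @return A `session_config` (for `read_config`); invisibly `path` (for
#'   `write_config`).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- session_config()
  for (f in names(defaults)) if (!is.null(raw[[f]])) defaults[[f]] <- raw[[f]]
  session_config(
    sensor_weight = defaults$sensor_weight,
    camunda_compat = defaults$camunda_compat,
    knowledge_source = defaults$knowledge_source,
    first_stage_exception = defaults$first_stage_exception,
    seed = defaults$seed
  )
}

#' @rdname read_config
#' @param config A `session_config` to serialize.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# deterministic local RNG scope; restores the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
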