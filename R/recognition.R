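# Situation recognition: interpret a simulated sensor observation through
# situation rules, then enrich the sensor-only distribution with process
# knowledge.  The fusion is a convex combination: a configurable impact
# weight splits the influence between sensor knowledge (default 80%) and
# process knowledge (default 20%), the latter entering as a uniform prior
# over the next possible steps.

#' Create a sensor observation
#'
#' One time-stamped simulated observation: the instrument set in use, actor
#' positions, and/or a direct step-name label.  At least one of the three
#' must be present.
#'
#' @param time Minutes since intervention start.
#' @param instruments Character vector of instrument names.
#' @param positions Named list or character vector mapping actor to zone.
#' @param step_label Directly observed step name, or `NA`.
#' @return A `sensor_observation`.
#' @export
sensor_observation <- function(time, instruments = character(0),
                               positions = list(), step_label = NA_character_) {
  positions <- as.list(positions)
  if (!length(instruments) && !length(positions) && is.na(step_label))
    sf_validation_error("observation must carry instruments, positions or a step label")
  structure(
    list(time = as.numeric(time), instruments = as.character(instruments),
         positions = positions, step_label = as.character(step_label)),
    class = "sensor_observation"
  )
}

#' Create a situation rule
#'
#' A rule maps a sensor signature (instrument subset and/or actor positions,
#' or a direct step label) to a target step with a base score.
#'
#' @param rule_id Identifier.
#' @param target_step Step id the rule votes for.
#' @param instrument_match Instruments that must all be present.
#' @param position_match Named list actor -> zone that must all match.
#' @param label_match Step label that must equal the observation's label.
#' @param base_score Score contributed when the rule fires, in (0, 1].
#' @return A `situation_rule`.
#' @export
situation_rule <- function(rule_id, target_step, instrument_match = character(0),
                           position_match = list(), label_match = NA_character_,
                           base_score = 1) {
  if (!(base_score > 0 && base_score <= 1))
    sf_validation_error("base_score must lie in (0, 1]")
  structure(
    list(rule_id = as.character(rule_id), target_step = as.character(target_step),
         instrument_match = as.character(instrument_match),
         position_match = as.list(position_match),
         label_match = as.character(label_match),
         base_score = as.numeric(base_score)),
    class = "situation_rule"
  )
}

rule_fires <- function(rule, obs) {
  if (!is.na(rule$label_match))
    return(identical(rule$label_match, obs$step_label))
  has_signature <- length(rule$instrument_match) || length(rule$position_match)
  if (!has_signature) return(FALSE)
  if (length(rule$instrument_match) &&
      !all(rule$instrument_match %in% obs$instruments)) return(FALSE)
  if (length(rule$position_match)) {
    for (actor in names(rule$position_match)) {
      if (!identical(obs$positions[[actor]], rule$position_match[[actor]]))
        return(FALSE)
    }
  }
  TRUE
}

#' Sensor-only situation scores
#'
#' Every firing rule contributes its base score to its target step; a direct
#' step-label observation scores its named step 1.0.  Scores are normalized
#' to a distribution.  An empty result signals "no sensor evidence".
#'
#' @param obs A [sensor_observation()].
#' @param rules List of [situation_rule()] objects.
#' @return Named numeric vector of step scores summing to 1, or an empty
#'   vector when nothing fires.
#' @export
score_sensors <- function(obs, rules) {
  scores <- numeric(0)
  add <- function(step, s) {
    scores[step] <<- (if (is.na(scores[step])) 0 else scores[step]) + s
  }
  if (!is.na(obs$step_label)) add(obs$step_label, 1.0)
  for (r in rules) {
    if (rule_fires(r, obs)) add(r$target_step, r$base_score)
  }
  # a direct label and its label rule vote for the same step; cap at one vote
  if (!is.na(obs$step_label) && !is.na(scores[obs$step_label]) &&
      scores[obs$step_label] > 1) scores[obs$step_label] <- 1.0
  if (!length(scores) || sum(scores) == 0) return(stats::setNames(numeric(0), character(0)))
  scores / sum(scores)
}

#' Impact configuration for knowledge fusion
#'
#' @param sensor_weight Fraction in `[0, 1]` of the sensor knowledge's
#'   influence; process knowledge receives the complement.  Default 0.8/0.2.
#' @return An `impact_config` with `sensor_weight` and `process_weight`.
#' @export
impact_config <- function(sensor_weight = 0.8) {
  if (is.na(sensor_weight) || sensor_weight < 0 || sensor_weight > 1)
    sf_validation_error("sensor_weight must lie in [0, 1]")
  structure(list(sensor_weight = as.numeric(sensor_weight),
                 process_weight = 1 - as.numeric(sensor_weight)),
            class = "impact_config")
}

#' Fuse sensor scores with process knowledge
#'
#' `fused(c) = sensor_weight * p_sensor(c) + process_weight * q(c)` where `q`
#' is uniform over the next possible steps (plus the current step) and zero
#' elsewhere; the result is renormalized.  Ties at the maximum break
#' lexically by step id.
#'
#' @param sensor_scores Named numeric distribution from [score_sensors()]
#'   (may be empty).
#' @param pk A `process_knowledge` object (or any list with `next_steps` and
#'   `reasonable`).
#' @param impact An [impact_config()].
#' @param current Currently running step id (included in the process
#'   support), or `NULL`.
#' @param level Recognition granularity label.
#' @return A `situation_knowledge` object: `candidates` (named distribution),
#'   `best`, `best_probability`, `reasonable`, `level`.
#' @export
fuse <- function(sensor_scores, pk, impact = impact_config(), current = NULL,
                 level = "step") {
  support <- sort(unique(c(pk$next_steps, current)))
  cand <- sort(unique(c(names(sensor_scores), support)))
  if (!length(cand)) {
    return(structure(
      list(candidates = stats::setNames(numeric(0), character(0)),
           best = NA_character_, best_probability = NA_real_,
           reasonable = FALSE, level = level),
      class = "situation_knowledge"
    ))
  }
  p <- stats::setNames(rep(0, length(cand)), cand)
  if (length(sensor_scores)) p[names(sensor_scores)] <- sensor_scores
  q <- stats::setNames(rep(0, length(cand)), cand)
  if (length(support)) q[support] <- 1 / length(support)
  fused <- impact$sensor_weight * p + impact$process_weight * q
  if (sum(fused) == 0) fused[] <- 1 / length(fused) else fused <- fused / sum(fused)
  best <- names(fused)[order(-fused, names(fused))][1]
  structure(
    list(candidates = fused, best = best,
         best_probability = unname(fused[best]),
         reasonable = isTRUE(pk$reasonable), level = level),
    class = "situation_knowledge"
  )
}

#' Recognize the situation from one observation
#'
#' Pipeline: sensor scoring, process-knowledge lookup on the (BPMN) knowledge
#' model, fusion, and reasonableness of the winning candidate.  Phase-level
#' recognition is derived as the phase containing the best step.
#'
#' @param obs A [sensor_observation()].
#' @param model The BPMN [process_model()] used as knowledge source.
#' @param trace Completed step ids so far.
#' @param rules List of [situation_rule()] objects.
#' @param impact An [impact_config()].
#' @param current The currently running step, or `NULL`.
#' @param camunda_compat Engine-compatibility flag for knowledge replay.
#' @return A `situation_knowledge` with additional fields `completable`
#'   (running instances whose completion activates the best candidate) and
#'   `phase` (phase id containing the best step, or `NA`).
#' @export
recognize <- function(obs, model, trace, rules, impact = impact_config(),
                      current = NULL, camunda_compat = TRUE) {
  sensor <- score_sensors(obs, rules)
  nxt <- knowledge_next_steps(model, trace, current, camunda_compat)
  pk0 <- list(next_steps = nxt, reasonable = TRUE)
  sk <- fuse(sensor, pk0, impact, current = current)
  if (is.na(sk$best)) {
    sk$completable <- character(0)
    sk$phase <- NA_character_
    sk$reasonable <- FALSE
    return(sk)
  }
  running <- sort(unique(c(nxt, current)))
  pk <- completable_instances(model, effective_trace(model, trace, current, camunda_compat),
                              sk$best, running, camunda_compat)
  sk$reasonable <- pk$reasonable ||
    (!is.null(current) && identical(sk$best, current))
  sk$completable <- pk$completable
  sk$phase <- phase_of_step(model, sk$best)
  sk
}

# Next steps seen from "current is running": replay the trace with the
# current step hypothetically completed; fall back to the bare trace when the
# hypothetical prefix is not valid on the knowledge model.
knowledge_next_steps <- function(model, trace, current, camunda_compat = TRUE) {
  tryCatch(
    dynamic_next_steps(model, effective_trace(model, trace, current, camunda_compat),
                       camunda_compat),
    surgflow_error = function(e) character(0)
  )
}

effective_trace <- function(model, trace, current, camunda_compat = TRUE) {
  if (is.null(current) || is.na(current)) return(trace)
  ok <- tryCatch({
    replay_trace(model, c(trace, current), camunda_compat); TRUE
  }, surgflow_error = function(e) FALSE)
  if (ok) c(trace, current) else trace
}

phase_of_step <- function(model, step_id) {
  for (n in model$nodes) {
    if (n$kind == "sub_process") {
      kids <- vapply(n$children, `[[`, character(1), "node_id")
      if (step_id %in% kids) return(n$node_id)
    }
  }
  NA_character_
}

#' @export
print.situation_knowledge <- function(x, ...) {
  cat(sprintf("<situation_knowledge> best=%s (p=%.3f, %s)\n",
              x$best, x$best_probability,
              if (isTRUE(x$reasonable)) "reasonable" else "not reasonable"))
  invisible(x)
}
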