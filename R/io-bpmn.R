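# BPMN 2.0 XML reader / writer for the supported element subset.
#
# The dialect is plain OMG BPMN (MODEL namespace) without vendor extension
# attributes.  Package-specific annotations live in the documented extension
# namespace `urn:surgflow:extensions`: an <sf:expectedDuration> extension
# element (minutes) and an sf:optional attribute marking bypassable tasks.
# Diagram-interchange sections are ignored on read and never written.

BPMN_NS <- "http://www.omg.org/spec/BPMN/20100524/MODEL"
SF_NS <- "urn:surgflow:extensions"

BPMN_ELEMENT_MAP <- c(
  startEvent = "start_event", endEvent = "end_event", userTask = "user_task",
  exclusiveGateway = "xor_gateway", parallelGateway = "and_gateway",
  subProcess = "sub_process", callActivity = "call_activity",
  boundaryEvent = "signal_boundary_event"
)
BPMN_SCAFFOLD <- c("definitions", "process", "sequenceFlow", "extensionElements",
                   "expectedDuration", "signalEventDefinition")
DI_NS_HINTS <- c("BPMN/20100524/DI", "DD/20100524", "CMMN/20151109/DI",
                 "CMMN/20151109/CMMNDI")

read_xml_checked <- function(path) {
  if (!file.exists(path)) sf_parse_error(sprintf("file not found: %s", path))
  tryCatch(
    xml2::read_xml(path),
    error = function(e) sf_parse_error(sprintf("malformed XML in %s: %s",
                                               path, conditionMessage(e)))
  )
}

#' Read a BPMN 2.0 process model
#'
#' Parses the supported subset (start/end events, user tasks, exclusive and
#' parallel gateways, sub-processes, call activities, signal boundary events,
#' sequence flows).  Elements outside the subset cause a structured
#' rejection naming the offending elements; diagram-interchange content is
#' ignored.
#'
#' @param path Path to a `.bpmn` file.
#' @return A validated [process_model()].
#' @export
read_bpmn <- function(path) {
  doc <- read_xml_checked(path)
  defs <- xml2::xml_find_first(doc, "/*")
  if (xml2::xml_name(defs) != "definitions")
    sf_parse_error(sprintf("%s: root element is <%s>, expected <definitions>",
                           path, xml2::xml_name(defs)))
  proc <- xml2::xml_find_first(doc, ".//*[local-name()='process']")
  if (inherits(proc, "xml_missing"))
    sf_parse_error(sprintf("%s: no <process> element", path))
  reject_unknown_bpmn(doc, path)
  parsed <- parse_bpmn_level(proc)
  gran <- xml2::xml_attr(proc, "granularity", ns = character())
  if (is.na(gran)) {
    kinds <- vapply(parsed$nodes, `[[`, character(1), "kind")
    gran <- if (any(kinds == "sub_process")) "two_level" else "one_level"
  }
  process_model(
    model_id = xml2::xml_attr(proc, "id"),
    name = attr_or(proc, "name", xml2::xml_attr(proc, "id")),
    nodes = parsed$nodes, flows = parsed$flows, granularity = gran
  )
}

attr_or <- function(node, attr, default = "") {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) default else v
}

reject_unknown_bpmn <- function(doc, path) {
  all_el <- xml2::xml_find_all(doc, "//*")
  names <- xml2::xml_name(all_el)
  ns_map <- xml2::xml_ns(doc)
  qualified <- xml2::xml_name(all_el, ns = ns_map)
  # drop anything living in a diagram-interchange namespace
  prefixes <- sub(":.*$", "", qualified)
  di_prefixes <- names(ns_map)[vapply(ns_map, function(u)
    any(vapply(DI_NS_HINTS, grepl, logical(1), x = u, fixed = TRUE)), logical(1))]
  keep <- !(prefixes %in% di_prefixes & grepl(":", qualified))
  names <- names[keep]
  known <- c(names(BPMN_ELEMENT_MAP), BPMN_SCAFFOLD)
  bad <- setdiff(unique(names), known)
  if (length(bad)) sf_unsupported_element(bad, path)
}

parse_bpmn_level <- function(level_node) {
  children <- xml2::xml_children(level_node)
  nodes <- list(); flows <- list()
  for (ch in children) {
    nm <- xml2::xml_name(ch)
    if (nm == "sequenceFlow") {
      flows[[length(flows) + 1L]] <- sequence_flow(
        flow_id = xml2::xml_attr(ch, "id"),
        source = xml2::xml_attr(ch, "sourceRef"),
        target = xml2::xml_attr(ch, "targetRef"),
        label = attr_or(ch, "name", "")
      )
    } else if (nm == "extensionElements") {
      next
    } else if (nm %in% names(BPMN_ELEMENT_MAP)) {
      nodes[[length(nodes) + 1L]] <- parse_bpmn_node(ch)
    }
  }
  list(nodes = nodes, flows = flows)
}

parse_bpmn_node <- function(ch) {
  nm <- xml2::xml_name(ch)
  kind <- BPMN_ELEMENT_MAP[[nm]]
  if (kind == "signal_boundary_event") {
    sig <- xml2::xml_find_first(ch, ".//*[local-name()='signalEventDefinition']")
    if (inherits(sig, "xml_missing"))
      sf_unsupported_element("boundaryEvent without signalEventDefinition",
                             xml2::xml_attr(ch, "id"))
  }
  dur <- xml2::xml_find_first(
    ch, "./*[local-name()='extensionElements']/*[local-name()='expectedDuration']")
  dur <- if (inherits(dur, "xml_missing")) NA_real_ else
    as.numeric(xml2::xml_text(dur))
  nested <- if (kind == "sub_process") parse_bpmn_level(ch) else
    list(nodes = list(), flows = list())
  flow_node(
    node_id = xml2::xml_attr(ch, "id"), kind = kind,
    name = attr_or(ch, "name", ""),
    optional_step = identical(xml2::xml_attr(ch, "optional"), "true"),
    expected_duration = dur,
    children = nested$nodes, child_flows = nested$flows,
    called_case = if (kind == "call_activity")
      xml2::xml_attr(ch, "calledElement") else NA_character_,
    attached_to = if (kind == "signal_boundary_event")
      xml2::xml_attr(ch, "attachedToRef") else NA_character_
  )
}

#' Write a process model as BPMN 2.0 XML
#'
#' Inverse of [read_bpmn()]: `read_bpmn(write_bpmn(m, f))` is structurally
#' identical to `m`.
#'
#' @param model A [process_model()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_bpmn <- function(model, path) {
  validate_process_model(model)
  doc <- xml2::xml_new_root(
    "definitions",
    xmlns = BPMN_NS, "xmlns:sf" = SF_NS,
    id = paste0("defs_", model$model_id),
    targetNamespace = "urn:surgflow:models"
  )
  proc <- xml2::xml_add_child(doc, "process", id = model$model_id,
                              name = model$name, isExecutable = "true")
  xml2::xml_set_attr(proc, "sf:granularity", model$granularity)
  write_bpmn_level(proc, model$nodes, model$flows)
  xml2::write_xml(doc, path)
  invisible(path)
}

bpmn_tag_for <- function(kind) names(BPMN_ELEMENT_MAP)[BPMN_ELEMENT_MAP == kind]

write_bpmn_level <- function(parent, nodes, flows) {
  for (n in nodes) {
    el <- xml2::xml_add_child(parent, bpmn_tag_for(n$kind), id = n$node_id)
    if (nzchar(n$name)) xml2::xml_set_attr(el, "name", n$name)
    if (n$optional_step) xml2::xml_set_attr(el, "sf:optional", "true")
    if (n$kind == "call_activity")
      xml2::xml_set_attr(el, "calledElement", n$called_case)
    if (n$kind == "signal_boundary_event") {
      xml2::xml_set_attr(el, "attachedToRef", n$attached_to)
      xml2::xml_add_child(el, "signalEventDefinition",
                          id = paste0(n$node_id, "_def"))
    }
    if (!is.na(n$expected_duration)) {
      ext <- xml2::xml_add_child(el, "extensionElements")
      xml2::xml_add_child(ext, "sf:expectedDuration",
                          format(n$expected_duration, scientific = FALSE))
    }
    if (n$kind == "sub_process") write_bpmn_level(el, n$children, n$child_flows)
  }
  for (f in flows) {
    el <- xml2::xml_add_child(parent, "sequenceFlow", id = f$flow_id,
                              sourceRef = f$source, targetRef = f$target)
    if (nzchar(f$label)) xml2::xml_set_attr(el, "name", f$label)
  }
  invisible(parent)
}
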