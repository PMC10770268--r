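# CMMN 1.1 XML reader / writer for the supported element subset.
#
# Plan items reference their definitions (human task, stage, event listener);
# stage definitions nest further plan items.  Sentries carry plan-item
# on-parts restricted to the "complete" standard event.  Required and manual
# activation rules are markers, so their condition expressions are restricted
# to the literals true/false; anything else is an unsupported-rule error.

CMMN_NS <- "http://www.omg.org/spec/CMMN/20151109/MODEL"

CMMN_DEF_MAP <- c(humanTask = "human_task", stage = "stage",
                  eventListener = "event_listener")
CMMN_SCAFFOLD <- c("definitions", "case", "casePlanModel", "planItem",
                   "entryCriterion", "itemControl", "requiredRule",
                   "manualActivationRule", "condition", "sentry",
                   "planItemOnPart", "standardEvent", "extensionElements",
                   "expectedDuration")

#' Read a CMMN 1.1 case model
#'
#' Parses the supported subset (case plan model, stages, human tasks, event
#' listeners, sentries with `complete` on-parts, constant required /
#' manual-activation rules).
#'
#' @param path Path to a `.cmmn` file.
#' @return A validated [case_model()].
#' @export
read_cmmn <- function(path) {
  doc <- read_xml_checked(path)
  defs <- xml2::xml_find_first(doc, "/*")
  if (xml2::xml_name(defs) != "definitions")
    sf_parse_error(sprintf("%s: root element is <%s>, expected <definitions>",
                           path, xml2::xml_name(defs)))
  all_names <- unique(xml2::xml_name(xml2::xml_find_all(doc, "//*")))
  bad <- setdiff(all_names, c(names(CMMN_DEF_MAP), CMMN_SCAFFOLD))
  if (length(bad)) sf_unsupported_element(bad, path)
  case_el <- xml2::xml_find_first(doc, ".//*[local-name()='case']")
  if (inherits(case_el, "xml_missing"))
    sf_parse_error(sprintf("%s: no <case> element", path))
  plan <- xml2::xml_find_first(case_el, "./*[local-name()='casePlanModel']")
  if (inherits(plan, "xml_missing"))
    sf_parse_error(sprintf("%s: no <casePlanModel> element", path))
  case_model(
    case_id = xml2::xml_attr(case_el, "id"),
    name = attr_or(case_el, "name", xml2::xml_attr(case_el, "id")),
    plan_items = parse_cmmn_stage_body(plan)
  )
}

# One containment level: pair <planItem> references with their definitions
# and sentries defined at the same level.
parse_cmmn_stage_body <- function(container) {
  children <- xml2::xml_children(container)
  nms <- xml2::xml_name(children)
  defs <- list(); sentries <- list()
  for (i in seq_along(children)) {
    ch <- children[[i]]
    if (nms[[i]] %in% names(CMMN_DEF_MAP)) defs[[xml2::xml_attr(ch, "id")]] <- ch
    if (nms[[i]] == "sentry") sentries[[xml2::xml_attr(ch, "id")]] <- ch
  }
  items <- list()
  for (i in seq_along(children)) {
    if (nms[[i]] != "planItem") next
    pi_el <- children[[i]]
    def_ref <- xml2::xml_attr(pi_el, "definitionRef")
    def <- defs[[def_ref]]
    if (is.null(def))
      sf_validation_error(sprintf("plan item '%s' references unknown definition '%s'",
                                  xml2::xml_attr(pi_el, "id"), def_ref))
    kind <- CMMN_DEF_MAP[[xml2::xml_name(def)]]
    crit <- lapply(
      xml2::xml_find_all(pi_el, "./*[local-name()='entryCriterion']"),
      function(ec) {
        sref <- xml2::xml_attr(ec, "sentryRef")
        sen <- sentries[[sref]]
        if (is.null(sen))
          sf_validation_error(sprintf("entry criterion references unknown sentry '%s'", sref))
        parse_cmmn_sentry(sen)
      }
    )
    rules <- parse_item_control(pi_el)
    dur <- xml2::xml_find_first(
      def, "./*[local-name()='extensionElements']/*[local-name()='expectedDuration']")
    dur <- if (inherits(dur, "xml_missing")) NA_real_ else
      as.numeric(xml2::xml_text(dur))
    items[[length(items) + 1L]] <- plan_item(
      item_id = xml2::xml_attr(pi_el, "id"), kind = kind,
      name = attr_or(def, "name", ""),
      required = rules$required, manual_activation = rules$manual_activation,
      entry_criteria = crit,
      children = if (kind == "stage") parse_cmmn_stage_body(def) else list(),
      expected_duration = dur
    )
  }
  items
}

parse_cmmn_sentry <- function(sen) {
  on_parts <- xml2::xml_find_all(sen, "./*[local-name()='planItemOnPart']")
  sources <- character(0)
  for (op in on_parts) {
    ev <- xml2::xml_text(
      xml2::xml_find_first(op, "./*[local-name()='standardEvent']"))
    if (!identical(ev, "complete"))
      sf_abort(sprintf("sentry '%s': unsupported standard event '%s'",
                       xml2::xml_attr(sen, "id"), ev),
               class = "surgflow_unsupported_rule")
    sources <- c(sources, xml2::xml_attr(op, "sourceRef"))
  }
  sentry(xml2::xml_attr(sen, "id"), sources)
}

parse_item_control <- function(pi_el) {
  rule_value <- function(rule_name, default) {
    node <- xml2::xml_find_first(
      pi_el, sprintf("./*[local-name()='itemControl']/*[local-name()='%s']", rule_name))
    if (inherits(node, "xml_missing")) return(default)
    cond <- xml2::xml_find_first(node, "./*[local-name()='condition']")
    txt <- if (inherits(cond, "xml_missing")) "true" else trimws(xml2::xml_text(cond))
    if (!txt %in% c("true", "false"))
      sf_abort(sprintf("item '%s': non-constant %s expression '%s'",
                       xml2::xml_attr(pi_el, "id"), rule_name, txt),
               class = "surgflow_unsupported_rule")
    identical(txt, "true")
  }
  list(required = rule_value("requiredRule", TRUE),
       manual_activation = rule_value("manualActivationRule", FALSE))
}

#' Write a case model as CMMN 1.1 XML
#'
#' Inverse of [read_cmmn()]: `read_cmmn(write_cmmn(m, f))` is structurally
#' identical to `m`.
#'
#' @param case A [case_model()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cmmn <- function(case, path) {
  validate_case_model(case)
  doc <- xml2::xml_new_root(
    "definitions",
    xmlns = CMMN_NS, "xmlns:sf" = SF_NS,
    id = paste0("defs_", case$case_id),
    targetNamespace = "urn:surgflow:models"
  )
  case_el <- xml2::xml_add_child(doc, "case", id = case$case_id, name = case$name)
  plan <- xml2::xml_add_child(case_el, "casePlanModel",
                              id = paste0(case$case_id, "_plan"),
                              name = case$name)
  write_cmmn_stage_body(plan, case$plan_items)
  xml2::write_xml(doc, path)
  invisible(path)
}

cmmn_tag_for <- function(kind) names(CMMN_DEF_MAP)[CMMN_DEF_MAP == kind]

write_cmmn_stage_body <- function(container, items) {
  for (it in items) {
    pi_el <- xml2::xml_add_child(container, "planItem", id = it$item_id,
                                 definitionRef = paste0("def_", it$item_id))
    for (s in it$entry_criteria) {
      xml2::xml_add_child(pi_el, "entryCriterion",
                          id = paste0("crit_", s$sentry_id),
                          sentryRef = s$sentry_id)
    }
    ic <- xml2::xml_add_child(pi_el, "itemControl")
    rr <- xml2::xml_add_child(ic, "requiredRule",
                              id = paste0(it$item_id, "_required"))
    xml2::xml_add_child(rr, "condition", if (it$required) "true" else "false")
    mr <- xml2::xml_add_child(ic, "manualActivationRule",
                              id = paste0(it$item_id, "_manual"))
    xml2::xml_add_child(mr, "condition",
                        if (it$manual_activation) "true" else "false")
    for (s in it$entry_criteria) {
      sen <- xml2::xml_add_child(container, "sentry", id = s$sentry_id)
      for (k in seq_along(s$on_parts)) {
        op <- xml2::xml_add_child(sen, "planItemOnPart",
                                  id = sprintf("%s_on_%d", s$sentry_id, k),
                                  sourceRef = s$on_parts[[k]]$source)
        xml2::xml_add_child(op, "standardEvent", s$on_parts[[k]]$event)
      }
    }
    def <- xml2::xml_add_child(container, cmmn_tag_for(it$kind),
                               id = paste0("def_", it$item_id))
    if (nzchar(it$name)) xml2::xml_set_attr(def, "name", it$name)
    if (!is.na(it$expected_duration)) {
      ext <- xml2::xml_add_child(def, "extensionElements")
      xml2::xml_add_child(ext, "sf:expectedDuration",
                          format(it$expected_duration, scientific = FALSE))
    }
    if (it$kind == "stage") write_cmmn_stage_body(def, it$children)
  }
  invisible(container)
}

#' Read a combination-model directory
#'
#' A combination bundle is a directory holding exactly one root `.bpmn` file
#' plus the `.cmmn` files its call activities reference.
#'
#' @param dir Directory path.
#' @return A [combination_model()]; style is inferred from the root process
#'   (`"mixed"` when user tasks appear at root level, `"structured"` otherwise).
#' @export
read_combination <- function(dir) {
  bpmn_files <- list.files(dir, pattern = "\\.bpmn$", full.names = TRUE)
  if (length(bpmn_files) != 1L)
    sf_parse_error(sprintf("expected exactly one .bpmn file in %s, found %d",
                           dir, length(bpmn_files)))
  root <- read_bpmn(bpmn_files[[1]])
  cases <- list()
  for (f in list.files(dir, pattern = "\\.cmmn$", full.names = TRUE)) {
    cs <- read_cmmn(f)
    cases[[cs$case_id]] <- cs
  }
  kinds <- vapply(all_nodes_flat(root), `[[`, character(1), "kind")
  style <- if (any(kinds == "user_task")) "mixed" else "structured"
  combination_model(style = style, root = root, cases = cases)
}

#' Write a combination model as a bundle directory
#'
#' @param model A [combination_model()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_combination <- function(model, dir) {
  validate_combination_model(model)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bpmn(model$root, file.path(dir, paste0(model$root$model_id, ".bpmn")))
  for (cs in model$cases)
    write_cmmn(cs, file.path(dir, paste0(cs$case_id, ".cmmn")))
  invisible(dir)
}
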