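# DDI 3.2 mapping, coverage appraisal, and StudyUnit export.
#
# The mapping table is packaged data, not code, so governance stakeholders
# can audit it. Each model element has exactly one fate under DDI 3.2:
#   direct      one or more DDI elements carry it natively (never via Note)
#   workaround  a Note attached to a maintainable object carries it,
#               possibly alongside a host DDI element
#   unmapped    DDI offers nothing; exported only in the extension block

#' Load the packaged model-to-DDI mapping table
#'
#' Reads the packaged table mapping every registry element to its DDI 3.2
#' fate and checks its integrity: the table and registry must be in
#' bijection, direct mappings must name DDI elements other than `Note`,
#' workarounds must include `Note`, and unmapped rows must name none.
#'
#' @param path mapping table JSON; defaults to the packaged table
#' @param registry registry the table must cover
#' @return data.frame of class `cl_ddi_table` with columns `model_element`,
#'   `category`, `note`, and list-column `ddi_elements`
#' @examples
#' tab <- load_mapping_table()
#' subset(tab, model_element == "full_name")
#' @export
load_mapping_table <- function(path = cl_extdata("ddi_mapping.json"),
                               registry = build_default_registry()) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tab <- data.frame(
    model_element = vapply(raw, `[[`, character(1), "model_element"),
    category = vapply(raw, `[[`, character(1), "category"),
    note = vapply(raw, `[[`, character(1), "note"),
    stringsAsFactors = FALSE
  )
  tab$ddi_elements <- lapply(raw, function(m) as_chr(m$ddi_elements))
  class(tab) <- c("cl_ddi_table", "data.frame")
  check_mapping_table(tab, registry)
  tab
}

check_mapping_table <- function(tab, registry) {
  if (anyDuplicated(tab$model_element)) {
    stop("mapping integrity: duplicate model_element entries: ",
         paste(unique(tab$model_element[duplicated(tab$model_element)]),
               collapse = ", "), call. = FALSE)
  }
  reg_ids <- names(registry$elements)
  missing <- setdiff(reg_ids, tab$model_element)
  if (length(missing) > 0) {
    stop("mapping integrity: registry element(s) absent from table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  orphan <- setdiff(tab$model_element, reg_ids)
  if (length(orphan) > 0) {
    stop("mapping integrity: mapped element(s) not in registry: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(tab))) {
    els <- tab$ddi_elements[[i]]
    ok <- switch(tab$category[i],
      direct = length(els) > 0 && !"Note" %in% els,
      workaround = "Note" %in% els,
      unmapped = length(els) == 0,
      FALSE
    )
    if (!ok) {
      stop("mapping integrity: row for ", tab$model_element[i],
           " violates the ", tab$category[i], " contract", call. = FALSE)
    }
  }
  invisible(tab)
}

#' Per-component DDI coverage report
#'
#' Tallies, for each of the model's four components, how many elements map
#' to DDI 3.2 directly, via the Note workaround, or not at all, with
#' percentages rounded to one decimal. The `mapped` share is direct plus
#' workaround. Percentages are invariant under element ordering, and an
#' empty registry yields an all-zero report.
#'
#' @param registry a `consent_registry`
#' @param table a mapping table from [load_mapping_table()]
#' @return data.frame of class `cl_coverage`: one row per component plus an
#'   `overall` row, with columns `component`, `n`, `direct`, `workaround`,
#'   `unmapped`, `direct_pct`, `workaround_pct`, `unmapped_pct`, `mapped_pct`
#' @examples
#' coverage_report(build_default_registry(), load_mapping_table())
#' @export
coverage_report <- function(registry = build_default_registry(),
                            table = load_mapping_table(registry = registry)) {
  check_mapping_table(table, registry)
  comp_of <- vapply(registry$elements, `[[`, character(1), "component")
  cat_of <- setNames(table$category, table$model_element)
  components <- registry$components
  rows <- lapply(c(components, "overall"), function(cmp) {
    ids <- if (cmp == "overall") names(comp_of) else names(comp_of)[comp_of == cmp]
    cats <- cat_of[ids]
    n <- length(ids)
    direct <- sum(cats == "direct")
    workaround <- sum(cats == "workaround")
    unmapped <- sum(cats == "unmapped")
    pct <- function(k) if (n == 0) 0 else round(100 * k / n, 1)
    data.frame(component = cmp, n = n, direct = direct,
               workaround = workaround, unmapped = unmapped,
               direct_pct = pct(direct), workaround_pct = pct(workaround),
               unmapped_pct = pct(unmapped),
               mapped_pct = pct(direct + workaround),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cl_coverage", "data.frame")
  out
}

#' @export
print.cl_coverage <- function(x, ...) {
  cat("DDI 3.2 mapping coverage by model component\n")
  df <- as.data.frame(x)
  df$direct_pct <- sprintf("%.1f%%", df$direct_pct)
  df$mapped_pct <- sprintf("%.1f%%", df$mapped_pct)
  print(df[, c("component", "n", "direct", "workaround", "unmapped",
               "direct_pct", "mapped_pct")], row.names = FALSE)
  invisible(x)
}

# --- StudyUnit export -----------------------------------------------------

note_payload <- function(element_id, value) {
  sprintf("model_element=%s; value=%s", element_id,
          as.character(jsonlite::toJSON(value, auto_unbox = TRUE,
                                        null = "null", digits = NA)))
}

add_note <- function(parent, element_id, value) {
  node <- xml2::xml_add_child(parent, "Note", attachedTo = element_id)
  xml2::xml_set_text(node, note_payload(value = value, element_id = element_id))
  invisible(node)
}

add_text_child <- function(parent, name, value, ...) {
  node <- xml2::xml_add_child(parent, name, ...)
  xml2::xml_set_text(node, scalar_to_text(value))
  invisible(node)
}

#' Export a consent-form instance as a DDI-style StudyUnit
#'
#' Emits a well-formed XML document rooted at `StudyUnit` using DDI 3.2
#' element names under a declared namespace. Directly mapped fields appear
#' under their DDI names; workaround fields are carried in `Note` elements
#' with a machine-recoverable `model_element=<id>; value=<json>` payload;
#' unmapped content (biological samples, free-form extensions) is emitted
#' only inside a clearly separated extension block under its own namespace.
#' Every lifecycle event supplied is emitted as a `LifecycleEvent` with an
#' `EventType` child; an instance without events yields none. The output is
#' namespace-tagged, well-formed XML; it is not validated against the
#' official DDI XSD.
#'
#' @param instance a valid [consent_form_instance()]
#' @param table mapping table (used to classify each emitted field)
#' @param events list of [lifecycle_event()]s attached to this instance
#' @param registry registry for the pre-export validation
#' @return raw vector of UTF-8 XML bytes
#' @export
export_study_unit <- function(instance,
                              table = load_mapping_table(registry = registry),
                              events = list(),
                              registry = build_default_registry()) {
  issues <- validate_instance(instance, registry)
  if (nrow(validation_errors(issues)) > 0) stop_invalid(issues, "export")

  doc <- xml2::xml_new_root("StudyUnit", xmlns = CL_DDI_NS,
                            id = instance$form_id)
  cit <- xml2::xml_add_child(doc, "Citation")
  add_text_child(cit, "Title", instance$study_name)
  add_text_child(doc, "Date", instance$date_of_completion)

  for (o in instance$organizations) {
    org <- xml2::xml_add_child(doc, "Organization",
                               subtype = o$subtype %||% "generic")
    add_text_child(org, "OrganizationName", o$organization_name)
    if (!is.null(o$ethics_approval_reference)) {
      add_note(org, "organization",
               list(ethics_approval_reference = o$ethics_approval_reference))
    }
  }

  for (p in instance$persons) {
    ind <- xml2::xml_add_child(doc, "Individual", id = p$id)
    add_text_child(ind, "FullName", p$full_name)
    if (!is.null(p$contact$telephone)) add_text_child(ind, "TelephoneNumber", p$contact$telephone)
    if (!is.null(p$contact$email)) add_text_child(ind, "Email", p$contact$email)
    if (!is.null(p$contact$location)) add_text_child(ind, "LocationName", p$contact$location)
    if (!is.null(p$contact$nationality)) add_text_child(ind, "Country", p$contact$nationality)
    if (!is.null(p$signature$date)) add_text_child(ind, "Date", p$signature$date)
    add_note(ind, p$kind %||% "person",
             cl_compact(list(role = p$role, kind = p$kind,
                             signed = p$signature$signed %||% FALSE,
                             date_of_birth = p$date_of_birth,
                             confirmation_of_understanding =
                               p$confirmation_of_understanding %||% FALSE)))
    if (!is.null(p$consents_on_behalf_of)) {
      add_note(ind, "consents_on_behalf_of", p$consents_on_behalf_of)
    }
  }

  if (length(instance$questions) > 0 || length(instance$responses) > 0) {
    dc <- xml2::xml_add_child(doc, "DataCollection")
    for (m in unique(vapply(instance$questions,
                            function(q) q$method_of_collection %||% "",
                            character(1)))) {
      if (nzchar(m)) add_text_child(dc, "ModeOfCollection", m)
    }
    for (q in instance$questions) {
      qi <- xml2::xml_add_child(dc, "QuestionItem", id = q$id,
                                kind = q$kind %||% "question",
                                responseDomain = q$responses$type %||% "free_text")
      add_text_child(qi, "QuestionText", q$text)
      if (!is.null(q$purpose)) add_text_child(qi, "Description", q$purpose)
      if (!is.null(q$logic)) {
        ite <- xml2::xml_add_child(qi, "IfThenElse")
        add_text_child(ite, "IfCondition",
                       sprintf("%s == %s", q$logic$question, q$logic$response))
      }
      if (!is.null(q$responses)) {
        if (identical(q$responses$type, "coded")) {
          cl <- xml2::xml_add_child(qi, "CodeList")
          if (!is.null(q$responses$code_list)) {
            add_text_child(cl, "CodeListName", q$responses$code_list)
          }
          for (v in q$responses$values %||% character(0)) {
            code <- xml2::xml_add_child(cl, "Code")
            add_text_child(code, "Category", v)
          }
          if (!is.null(q$responses$code_list)) {
            add_text_child(qi, "CodeListReference", q$responses$code_list)
          }
        } else {
          add_text_child(qi, "ResponseText", "")
        }
      }
    }
    for (qid in names(instance$responses)) {
      add_text_child(dc, "ResponseText", instance$responses[[qid]],
                     questionReference = qid)
    }
  }

  if (length(instance$scopes) > 0) {
    grp <- xml2::xml_add_child(doc, "CodeListGroup", name = "personal_records")
    for (s in instance$scopes) {
      cl <- xml2::xml_add_child(grp, "CodeList",
                                granted = scalar_to_text(s$granted %||% FALSE))
      if (isTRUE(s$future_contact)) {
        xml2::xml_set_attr(cl, "future_contact", "true")
      }
      add_text_child(cl, "CodeListName", s$category)
      for (part in s$economic_parts %||% character(0)) {
        code <- xml2::xml_add_child(cl, "Code")
        add_text_child(code, "Category", part)
      }
      for (t in s$health_temporal %||% character(0)) {
        add_text_child(cl, "TemporalCoverage", t)
      }
      for (hp in s$health_parts %||% character(0)) {
        add_note(cl, hp, list(granted = s$granted %||% FALSE))
      }
      if (!is.null(s$detail)) xml2::xml_set_attr(cl, "detail", s$detail)
    }
  }

  if (!is.null(instance$general$aim)) {
    add_text_child(doc, "Purpose", instance$general$aim)
  }
  if (!is.null(instance$general$undertakings)) {
    add_note(doc, "undertakings", instance$general$undertakings)
  }
  if (!is.null(instance$general$confirmatory_information)) {
    add_note(doc, "confirmatory_information",
             instance$general$confirmatory_information)
  }
  if (!is.null(instance$instructions_for_next_steps)) {
    add_text_child(doc, "Instruction", instance$instructions_for_next_steps)
  }

  for (d in instance$informational_documents) {
    om <- xml2::xml_add_child(doc, "OtherMaterial", type = d$type)
    add_note(om, "informational_document",
             cl_compact(list(accessibility = d$accessibility,
                             audience = d$audience, type = d$type)))
    st <- d$study
    if (!is.null(st) && length(cl_compact(st)) > 0) {
      cit <- xml2::xml_add_child(om, "Citation")
      if (!is.null(st$objectives)) add_text_child(cit, "Title", st$objectives)
      if (!is.null(st$aims)) add_text_child(cit, "Abstract", st$aims)
      if (!is.null(st$contact_details)) add_text_child(cit, "Email", st$contact_details)
      for (fb in st$funding_bodies %||% character(0)) {
        add_text_child(cit, "FundingInformation", fb)
      }
      if (!is.null(st$reviewers)) add_note(cit, "reviewers", st$reviewers)
    }
    if (!is.null(d$research)) add_note(om, "research", d$research)
    if (!is.null(d$withdrawal_procedure)) {
      add_text_child(om, "Description", d$withdrawal_procedure,
                     model = "withdrawal_procedure")
    }
    if (!is.null(d$data_flow_description)) {
      add_note(om, "data_flow_description", d$data_flow_description)
    }
  }

  for (e in events) {
    le <- xml2::xml_add_child(doc, "LifecycleEvent")
    add_text_child(le, "EventType", e$event_type)
    add_text_child(le, "Date", e$date)
    add_text_child(le, "AgentReference", e$actor$person_id)
    if (!is.null(e$target_scope)) {
      add_text_child(le, "Description",
                     paste(unlist(e$target_scope), collapse = "/"))
    }
  }

  # Unmapped model content and free-form extensions live in a clearly
  # separated non-DDI block under the project's extension namespace.
  ext_content <- list()
  bio <- lapply(instance$scopes, function(s) s$biological_samples)
  bio <- bio[!vapply(bio, is.null, logical(1))]
  if (length(bio) > 0) ext_content$biological_samples <- bio
  if (length(instance$extensions %||% list()) > 0) {
    ext_content$extensions <- instance$extensions
  }
  if (length(ext_content) > 0) {
    ext <- xml2::xml_add_child(doc, "ExtensionBlock", xmlns = CL_EXT_NS)
    xml2::xml_set_text(ext, as.character(
      jsonlite::toJSON(ext_content, auto_unbox = TRUE, null = "null",
                       digits = NA)))
  }

  charToRaw(enc2utf8(as.character(doc)))
}

#' Census of instance fields present in an exported StudyUnit
#'
#' Export totality check: every populated atomic field value of a valid
#' instance must appear somewhere in the StudyUnit output — under a direct
#' DDI element, inside a Note payload, or in the extension block.
#'
#' @param instance the instance that was exported
#' @param xml bytes returned by [export_study_unit()]
#' @return data.frame with columns `value` and `found`
#' @export
export_census <- function(instance, xml) {
  doc <- xml2::read_xml(rawToChar(xml))
  hay <- paste(
    paste(xml2::xml_text(xml2::xml_find_all(doc, "//*")), collapse = "\n"),
    paste(unlist(lapply(xml2::xml_find_all(doc, "//*"), function(n) {
      unlist(xml2::xml_attrs(n))
    })), collapse = "\n"),
    sep = "\n"
  )
  values <- atomic_values(as_plain_instance(instance))
  values <- unique(values[nzchar(values)])
  data.frame(value = values,
             found = vapply(values, function(v) grepl(v, hay, fixed = TRUE),
                            logical(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

atomic_values <- function(x) {
  if (is.null(x)) return(character(0))
  if (is.list(x)) return(unlist(lapply(x, atomic_values), use.names = FALSE))
  if (is.logical(x)) return(if (isTRUE(x)) "true" else "false")
  as.character(x)
}
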