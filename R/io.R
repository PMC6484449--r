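# Serialization of consent-form instances.
#
# JSON is the primary dialect: a canonical, stable-key-order object tree in
# which arrays are always arrays (even with one member) and optional absent
# fields are omitted. The XML dialect mirrors the same tree: element names
# are the model's canonical ids, repeated members of plain-string arrays are
# <item> elements, and the free-form extensions container is carried as
# embedded JSON. Encoding is UTF-8 throughout.

CL_XML_NS <- "urn:consentlink:instance:1.0"
CL_DDI_NS <- "ddi:instance:3_2"
CL_EXT_NS <- "urn:consentlink:extension:1.0"

ARRAY_FIELDS <- c("organizations", "persons", "questions", "scopes",
                  "informational_documents", "economic_parts",
                  "health_temporal", "health_parts", "values",
                  "funding_bodies")
BOOL_FIELDS <- c("granted", "signed", "confirmation_of_understanding",
                 "future_contact")
ITEM_NAMES <- c(organizations = "organization", persons = "person",
                questions = "question", scopes = "scope",
                informational_documents = "informational_document")

empty_object <- function() structure(list(), names = character(0))

# --- canonical plain form -------------------------------------------------

# The plain form is the serialization-ready tree: named lists for objects,
# unnamed lists for arrays, scalars elsewhere. Both dialects write and read
# exactly this form, so cross-format round trips are structural identities.
to_plain <- function(x, field = NULL) {
  if (is.null(x)) return(NULL)
  if (!is.null(field) && field %in% ARRAY_FIELDS) {
    return(lapply(unname(as.list(x)), to_plain))
  }
  if (is.list(x)) {
    x <- unclass(x)
    if (length(x) == 0) return(NULL) # empty objects are omitted, not emitted
    if (is.null(names(x))) return(lapply(x, to_plain))
    out <- list()
    for (k in names(x)) {
      v <- to_plain(x[[k]], field = k)
      if (!is.null(v)) out[[k]] <- v
    }
    if (length(out) == 0) return(NULL)
    return(out)
  }
  if (length(x) > 1) return(lapply(unname(as.list(x)), to_plain))
  x
}

as_plain_instance <- function(instance) {
  plain <- to_plain(unclass(instance))
  # required containers always present, even when empty
  for (k in c("organizations", "persons", "questions", "scopes",
              "informational_documents")) {
    if (is.null(plain[[k]])) plain[[k]] <- list()
  }
  if (is.null(plain$responses)) plain$responses <- empty_object()
  if (is.null(plain$extensions)) plain$extensions <- empty_object()
  order <- INSTANCE_SCHEMA$instance
  known <- intersect(order, names(plain))
  plain[c(known, setdiff(names(plain), order))]
}

as_chr <- function(x) {
  if (is.null(x) || length(x) == 0) return(character(0))
  vapply(x, function(v) as.character(v), character(1))
}

plain_to_instance <- function(plain) {
  persons <- lapply(plain$persons, function(p) {
    p$confirmation_of_understanding <- isTRUE(p$confirmation_of_understanding)
    if (!is.null(p$signature)) p$signature$signed <- isTRUE(p$signature$signed)
    structure(p, class = "cl_person")
  })
  organizations <- lapply(plain$organizations, function(o) {
    structure(o, class = "cl_organization")
  })
  questions <- lapply(plain$questions, function(q) {
    if (!is.null(q$responses$values)) q$responses$values <- as_chr(q$responses$values)
    structure(q, class = "cl_question")
  })
  scopes <- lapply(plain$scopes, function(s) {
    for (k in c("economic_parts", "health_temporal", "health_parts")) {
      if (!is.null(s[[k]])) s[[k]] <- as_chr(s[[k]])
    }
    s$granted <- isTRUE(s$granted)
    s$future_contact <- isTRUE(s$future_contact)
    structure(s, class = "cl_record_scope")
  })
  docs <- lapply(plain$informational_documents, function(d) {
    if (!is.null(d$study$funding_bodies)) {
      d$study$funding_bodies <- as_chr(d$study$funding_bodies)
    }
    structure(d, class = "cl_infodoc")
  })
  responses <- plain$responses %||% empty_object()
  structure(list(
    form_id = plain$form_id,
    study_name = plain$study_name,
    organizations = organizations,
    persons = persons,
    questions = questions,
    responses = responses,
    scopes = scopes,
    date_of_completion = plain$date_of_completion,
    general = plain$general %||% empty_object(),
    instructions_for_next_steps = plain$instructions_for_next_steps,
    informational_documents = docs,
    extensions = plain$extensions %||% empty_object()
  ), class = "cl_instance")
}

#' Structural equality of two instances
#'
#' Compares the canonical serialized forms, so ordering of optional absent
#' fields and attribute classes do not matter.
#'
#' @param a,b consent-form instances
#' @return logical
#' @export
instances_equal <- function(a, b) {
  identical(as_plain_instance(a), as_plain_instance(b))
}

# --- writing --------------------------------------------------------------

#' Serialize a consent-form instance
#'
#' Produces a deterministic document: identical instances always serialize
#' to identical bytes. Instances failing validation with error-severity
#' issues are refused; the error signalled carries the issue table
#' (see [condition_issues()]).
#'
#' @param instance a [consent_form_instance()]
#' @param format `"json"` (primary dialect) or `"xml"`
#' @param registry registry used for the pre-serialization validation
#' @param validate set `FALSE` to skip validation (used by internal tooling)
#' @return raw vector of UTF-8 document bytes
#' @examples
#' inst <- generate_instance(study_profile("generic"), seed = 1)
#' json <- write_instance(inst, "json")
#' identical(instances_equal(read_instance(json, "json"), inst), TRUE)
#' @export
write_instance <- function(instance, format = c("json", "xml"),
                           registry = build_default_registry(),
                           validate = TRUE) {
  format <- match.arg(format)
  if (validate) {
    issues <- validate_instance(instance, registry)
    if (nrow(validation_errors(issues)) > 0) stop_invalid(issues, "serialization")
  }
  plain <- as_plain_instance(instance)
  txt <- if (format == "json") {
    paste0(jsonlite::toJSON(plain, auto_unbox = TRUE, null = "null",
                            pretty = TRUE, digits = NA), "\n")
  } else {
    doc <- xml2::xml_new_root("consent_form", xmlns = CL_XML_NS)
    for (k in names(plain)) plain_to_xml(doc, k, plain[[k]], top = TRUE)
    as.character(doc)
  }
  charToRaw(enc2utf8(txt))
}

plain_to_xml <- function(parent, name, value, top = FALSE) {
  if (is.null(value)) return(invisible())
  if (top && identical(name, "extensions")) {
    node <- xml2::xml_add_child(parent, "extensions")
    xml2::xml_set_text(node, as.character(
      jsonlite::toJSON(value, auto_unbox = TRUE, null = "null", digits = NA)))
    return(invisible())
  }
  if (top && identical(name, "responses") && !is.null(names(value))) {
    # instance-level response map: question id -> value
    node <- xml2::xml_add_child(parent, "responses")
    for (qid in names(value)) {
      child <- xml2::xml_add_child(node, "response", question = qid)
      xml2::xml_set_text(child, as.character(value[[qid]]))
    }
    return(invisible())
  }
  if (is.list(value) && is.null(names(value))) {
    node <- xml2::xml_add_child(parent, name)
    item_name <- if (name %in% names(ITEM_NAMES)) ITEM_NAMES[[name]] else "item"
    for (v in value) {
      if (is.list(v)) {
        child <- xml2::xml_add_child(node, item_name)
        for (k in names(v)) plain_to_xml(child, k, v[[k]])
      } else {
        child <- xml2::xml_add_child(node, item_name)
        xml2::xml_set_text(child, scalar_to_text(v))
      }
    }
    return(invisible())
  }
  if (is.list(value)) {
    node <- xml2::xml_add_child(parent, name)
    for (k in names(value)) plain_to_xml(node, k, value[[k]])
    return(invisible())
  }
  node <- xml2::xml_add_child(parent, name)
  xml2::xml_set_text(node, scalar_to_text(value))
  invisible()
}

scalar_to_text <- function(v) {
  if (is.logical(v)) return(if (isTRUE(v)) "true" else "false")
  as.character(v)
}

# --- reading --------------------------------------------------------------

#' Read a consent-form instance document
#'
#' Accepts raw bytes (as produced by [write_instance()]), a single document
#' string, or a file path. Syntactically invalid documents raise a parse
#' error; structurally invalid documents raise a validation error carrying
#' the issue table.
#'
#' @param document raw vector, document string, or path to a file
#' @param format `"json"` or `"xml"`
#' @param registry registry used for post-parse validation
#' @param validate set `FALSE` to obtain the instance without validation
#' @return an object of class `cl_instance`
#' @export
read_instance <- function(document, format = c("json", "xml"),
                          registry = build_default_registry(),
                          validate = TRUE) {
  format <- match.arg(format)
  txt <- document_text(document)
  if (!nzchar(trimws(txt))) {
    stop("parse error: empty document", call. = FALSE)
  }
  plain <- if (format == "json") {
    jsonlite::fromJSON(txt, simplifyVector = FALSE)
  } else {
    xml_to_plain_instance(xml2::read_xml(txt))
  }
  inst <- plain_to_instance(plain)
  if (validate) {
    issues <- validate_instance(inst, registry)
    if (nrow(validation_errors(issues)) > 0) stop_invalid(issues, "read")
  }
  inst
}

document_text <- function(document) {
  if (is.raw(document)) {
    txt <- rawToChar(document)
    Encoding(txt) <- "UTF-8"
    return(txt)
  }
  if (is.character(document) && length(document) == 1) {
    if (!grepl("[{<\n]", document) && file.exists(document)) {
      return(paste(readLines(document, encoding = "UTF-8", warn = FALSE),
                   collapse = "\n"))
    }
    return(document)
  }
  if (is.character(document)) return(paste(document, collapse = "\n"))
  stop("document must be raw bytes, a string, or a file path", call. = FALSE)
}

xml_to_plain_instance <- function(doc) {
  root <- xml2::xml_root(doc)
  if (!identical(xml2::xml_name(root), "consent_form")) {
    stop("parse error: expected root element consent_form, found ",
         xml2::xml_name(root), call. = FALSE)
  }
  xml_object_to_plain(root, top = TRUE)
}

xml_object_to_plain <- function(node, top = FALSE) {
  out <- empty_object()
  for (child in xml2::xml_children(node)) {
    name <- xml2::xml_name(child)
    out[[name]] <- xml_value_to_plain(child, name, top = top)
  }
  out
}

xml_value_to_plain <- function(node, name, top = FALSE) {
  if (top && identical(name, "extensions")) {
    txt <- xml2::xml_text(node)
    if (!nzchar(trimws(txt))) return(empty_object())
    return(jsonlite::fromJSON(txt, simplifyVector = FALSE))
  }
  kids <- xml2::xml_children(node)
  if (top && identical(name, "responses")) {
    out <- empty_object()
    for (k in kids) out[[xml2::xml_attr(k, "question")]] <- xml2::xml_text(k)
    return(out)
  }
  if (name %in% ARRAY_FIELDS) {
    return(lapply(kids, function(k) {
      if (length(xml2::xml_children(k)) > 0) xml_object_to_plain(k)
      else xml2::xml_text(k)
    }))
  }
  if (length(kids) > 0) return(xml_object_to_plain(node))
  text_to_scalar(xml2::xml_text(node), name)
}

text_to_scalar <- function(txt, name) {
  if (name %in% BOOL_FIELDS) return(identical(txt, "true"))
  txt
}

# --- consent-store serialization -----------------------------------------

#' Read or write a consent store
#'
#' A store is serialized as a JSON object with an `instances` array in the
#' instance dialect and an `events` array of lifecycle events.
#'
#' @param store a [consent_store()]
#' @param path file path (for `write_store`) or path/string/raw (for
#'   `read_store`)
#' @param registry registry used to validate member instances
#' @return `read_store` returns a `cl_store`; `write_store` returns `path`
#'   invisibly
#' @export
write_store <- function(store, path, registry = build_default_registry()) {
  stopifnot(inherits(store, "cl_store"))
  plain <- list(
    instances = lapply(store$instances, as_plain_instance),
    events = lapply(store$events, function(e) to_plain(unclass(e)))
  )
  txt <- paste0(jsonlite::toJSON(plain, auto_unbox = TRUE, null = "null",
                                 pretty = TRUE, digits = NA), "\n")
  writeLines(txt, path, useBytes = TRUE, sep = "")
  invisible(path)
}

#' @rdname write_store
#' @export
read_store <- function(path, registry = build_default_registry()) {
  plain <- jsonlite::fromJSON(document_text(path), simplifyVector = FALSE)
  instances <- lapply(plain$instances %||% list(), plain_to_instance)
  store <- consent_store(instances = instances, registry = registry)
  for (e in plain$events %||% list()) {
    ev <- lifecycle_event(e$event_type, e$date, e$actor$form_id,
                          e$actor$person_id, target_scope = e$target_scope)
    store <- apply_event(store, ev)
  }
  store
}
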