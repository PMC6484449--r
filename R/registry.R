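#' The consent-metadata element registry
#'
#' The registry is the machine-readable form of the consent metadata model:
#' a set of named element definitions organized into four components
#' (`people`, `consent_form`, `personal_records`, `informational_material`),
#' related by *inheritance* (a child element acquires all of its ancestors'
#' attributes) and *aggregation* (composite elements are assembled from part
#' elements with cardinalities). Inheritance and aggregation keep the model
#' small: shared attributes such as the organization name are defined once on
#' a parent element, and composites such as the question block are declared
#' from their parts (logic, responses, purpose).
#'
#' `build_default_registry()` loads the registry packaged with consentlink,
#' which records the model in its final, post-evaluation state: the date of
#' completion lives on the consent form, people are specialized into
#' professional and non-professional, the economic record category is composed
#' of separate benefits-claims / NI-contributions / tax elements, and
#' biological samples form their own element with laboratory attributes.
#'
#' @param path path to a registry JSON file; defaults to the packaged registry.
#' @return an object of class `consent_registry`: a list with `elements`
#'   (named list of element definitions), `components`, and `version`.
#' @examples
#' reg <- build_default_registry()
#' reg
#' aggregate_parts(reg, "personal_records")$id
#' @export
build_default_registry <- function(path = cl_extdata("registry.json")) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  elements <- list()
  for (el in raw$elements) {
    def <- list(
      id = el$id,
      label = el$label,
      component = el$component,
      parent = el$parent,
      attributes = vapply(el$attributes, identity, character(1)),
      parts = lapply(el$parts, function(p) {
        list(id = p$id, min = p$min,
             max = if (identical(p$max, "unbounded")) Inf else p$max)
      })
    )
    if (!is.null(elements[[def$id]])) {
      stop("registry integrity: duplicate element id ", def$id, call. = FALSE)
    }
    elements[[def$id]] <- def
  }
  reg <- structure(
    list(
      version = raw$registry_version,
      components = unlist(raw$components),
      elements = elements
    ),
    class = "consent_registry"
  )
  check_registry(reg)
  reg
}

# Structural integrity: ids resolve, component values legal, both relation
# graphs acyclic. Called on every load so a hand-edited registry fails fast.
check_registry <- function(reg) {
  ids <- names(reg$elements)
  for (el in reg$elements) {
    if (!el$component %in% reg$components) {
      stop("registry integrity: element ", el$id, " has unknown component ",
           el$component, call. = FALSE)
    }
    if (!is.null(el$parent) && !el$parent %in% ids) {
      stop("registry integrity: parent of ", el$id, " not defined", call. = FALSE)
    }
    for (p in el$parts) {
      if (!p$id %in% ids) {
        stop("registry integrity: part ", p$id, " of ", el$id, " not defined",
             call. = FALSE)
      }
    }
  }
  assert_acyclic(reg, edges_of = function(el) {
    if (is.null(el$parent)) character(0) else el$parent
  }, relation = "inheritance")
  assert_acyclic(reg, edges_of = function(el) {
    vapply(el$parts, `[[`, character(1), "id")
  }, relation = "aggregation")
  invisible(reg)
}

# Kahn-style topological check over one of the two relation graphs.
assert_acyclic <- function(reg, edges_of, relation) {
  ids <- names(reg$elements)
  adj <- lapply(reg$elements, edges_of)
  state <- setNames(rep(0L, length(ids)), ids) # 0 unseen, 1 in stack, 2 done
  visit <- function(id) {
    if (state[[id]] == 1L) {
      stop("registry integrity: ", relation, " cycle through ", id, call. = FALSE)
    }
    if (state[[id]] == 2L) return(invisible())
    state[[id]] <<- 1L
    for (nb in adj[[id]]) visit(nb)
    state[[id]] <<- 2L
    invisible()
  }
  for (id in ids) visit(id)
  invisible(TRUE)
}

lookup_element <- function(registry, element_id) {
  stopifnot(inherits(registry, "consent_registry"))
  el <- registry$elements[[element_id]]
  if (is.null(el)) {
    stop("unknown element id: ", element_id, call. = FALSE)
  }
  el
}

#' Effective attribute set of an element
#'
#' The effective attributes of an element are its own attributes plus every
#' ancestor's, following inheritance links to the root. A root element's
#' effective attributes equal its own. For example, the academic institution
#' inherits the organization name and ethics approval reference from the
#' organization element.
#'
#' @param registry a `consent_registry`
#' @param element_id canonical element id
#' @return character vector of attribute names (sorted, unique)
#' @examples
#' reg <- build_default_registry()
#' effective_attributes(reg, "academic_institution")
#' @export
effective_attributes <- function(registry, element_id) {
  el <- lookup_element(registry, element_id)
  attrs <- el$attributes
  while (!is.null(el$parent)) {
    el <- lookup_element(registry, el$parent)
    attrs <- c(attrs, el$attributes)
  }
  sort(unique(attrs))
}

#' Direct aggregation parts of an element
#'
#' Returns the element's declared part-of children in declaration order, with
#' cardinalities. Leaf elements return a zero-row result. Cardinality follows
#' the model's rule that parts may repeat without restriction unless the
#' registry narrows them.
#'
#' @inheritParams effective_attributes
#' @return data.frame with columns `id`, `min`, `max` (`Inf` = unbounded)
#' @examples
#' reg <- build_default_registry()
#' aggregate_parts(reg, "questions")
#' @export
aggregate_parts <- function(registry, element_id) {
  el <- lookup_element(registry, element_id)
  data.frame(
    id = vapply(el$parts, `[[`, character(1), "id"),
    min = vapply(el$parts, function(p) as.numeric(p$min), numeric(1)),
    max = vapply(el$parts, function(p) as.numeric(p$max), numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.consent_registry <- function(x, ...) {
  cat("<consent_registry> version", x$version, "\n")
  comp <- vapply(x$elements, `[[`, character(1), "component")
  tab <- table(factor(comp, levels = x$components))
  cat(sprintf("  %d elements across %d components:\n",
              length(x$elements), length(x$components)))
  for (cn in names(tab)) cat(sprintf("    %-24s %d\n", cn, tab[[cn]]))
  invisible(x)
}

#' Elements of a registry as a data frame
#'
#' @inheritParams effective_attributes
#' @return data.frame with one row per element: `id`, `label`, `component`,
#'   `parent`, `n_attributes`, `n_parts`
#' @export
registry_elements <- function(registry) {
  stopifnot(inherits(registry, "consent_registry"))
  els <- registry$elements
  data.frame(
    id = vapply(els, `[[`, character(1), "id"),
    label = vapply(els, `[[`, character(1), "label"),
    component = vapply(els, `[[`, character(1), "component"),
    parent = vapply(els, function(e) e$parent %||% NA_character_, character(1)),
    n_attributes = vapply(els, function(e) length(e$attributes), integer(1)),
    n_parts = vapply(els, function(e) length(e$parts), integer(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Top-level record categories of the personal-records component
#'
#' The six record categories a participant may be asked to consent to link:
#' economic, education, legal, family, mobile phone usage, and health.
#'
#' @inheritParams effective_attributes
#' @return character vector of category ids in registry order
#' @export
record_categories <- function(registry = build_default_registry()) {
  aggregate_parts(registry, "personal_records")$id
}
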