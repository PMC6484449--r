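# Registry-driven validation of consent-form instances.
#
# Issue codes (all documented in the CLI help):
#   UNKNOWN_ELEMENT   a key not defined by the model outside the extensions container
#   NO_NON_PROFESSIONAL  no non-professional person on the form
#   KIND_ROLE_MISMATCH   person kind inconsistent with role
#   SELF_PROXY        a person consents on behalf of themselves
#   PROXY_TARGET_MISSING consents_on_behalf_of names a person not on the form
#   DUPLICATE_ID      duplicate person or question id
#   DATE_ORDER        a signature date follows the form's date of completion
#   BAD_DATE          a date is missing or not a valid ISO calendar date
#   LOGIC_ORDER       question logic references a question that does not precede it
#   DANGLING_RESPONSE a response key matches no question id
#   SCOPE_PART_MISMATCH  sub-parts set on a scope of the wrong category
#   BAD_ENUM          a field value outside its enumerated set
#   MISSING_FIELD     a required field is absent

ISSUE_CODES <- c("UNKNOWN_ELEMENT", "NO_NON_PROFESSIONAL", "KIND_ROLE_MISMATCH",
                 "SELF_PROXY", "PROXY_TARGET_MISSING", "DUPLICATE_ID",
                 "DATE_ORDER", "BAD_DATE", "LOGIC_ORDER", "DANGLING_RESPONSE",
                 "SCOPE_PART_MISMATCH", "BAD_ENUM", "MISSING_FIELD")

issue <- function(severity, code, path, message) {
  data.frame(severity = severity, code = code, path = path, message = message,
             stringsAsFactors = FALSE)
}

no_issues <- function() {
  data.frame(severity = character(0), code = character(0),
             path = character(0), message = character(0),
             stringsAsFactors = FALSE)
}

# Allowed keys per node of the instance dialect. Everything else must live
# under `extensions`: unknown elements are errors because silent extension
# defeats standardization.
INSTANCE_SCHEMA <- list(
  instance = c("form_id", "study_name", "organizations", "persons",
               "questions", "responses", "scopes", "date_of_completion",
               "general", "instructions_for_next_steps",
               "informational_documents", "extensions"),
  person = c("id", "full_name", "role", "kind", "contact", "date_of_birth",
             "signature", "confirmation_of_understanding",
             "consents_on_behalf_of"),
  contact = c("telephone", "email", "location", "nationality"),
  signature = c("signed", "date"),
  consents_on_behalf_of = c("person", "relationship"),
  organization = c("organization_name", "ethics_approval_reference", "subtype"),
  question = c("id", "text", "kind", "logic", "responses", "purpose",
               "method_of_collection"),
  logic = c("question", "response"),
  question_responses = c("type", "code_list", "values"),
  scope = c("category", "granted", "economic_parts", "health_temporal",
            "health_parts", "biological_samples", "future_contact", "detail"),
  biological_samples = c("type_of_test", "storage_of_sample", "lab_name",
                         "lab_site"),
  general = c("aim", "undertakings", "confirmatory_information"),
  informational_document = c("accessibility", "audience", "type", "study",
                             "research", "withdrawal_procedure",
                             "data_flow_description"),
  study = c("aims", "contact_details", "funding_bodies", "objectives",
            "reviewers")
)

check_keys <- function(node, schema_name, path) {
  extra <- setdiff(names(node), INSTANCE_SCHEMA[[schema_name]])
  if (length(extra) == 0) return(no_issues())
  do.call(rbind, lapply(extra, function(k) {
    issue("error", "UNKNOWN_ELEMENT", paste0(path, "/", k),
          sprintf("'%s' is not an element of the consent model; use the extensions container", k))
  }))
}

#' Validate a consent-form instance against the registry
#'
#' Checks the structural rules of the consent model: every key must be a
#' model element (or live under `extensions`), at least one non-professional
#' person is present, proxy-consent links resolve and are not reflexive,
#' person kinds match their roles, question logic only looks backwards in
#' form order, responses answer existing questions, scope sub-parts match
#' their category, and no signature date follows the form's date of
#' completion. An empty result means every invariant holds.
#'
#' @param instance a [consent_form_instance()] (or an instance read from disk)
#' @param registry a [build_default_registry()] registry
#' @return data.frame of issues with columns `severity`, `code`, `path`,
#'   `message`, ordered by `path`; zero rows when valid
#' @examples
#' inst <- generate_instance(study_profile("generic"), seed = 1)
#' validate_instance(inst, build_default_registry())
#' @export
validate_instance <- function(instance, registry = build_default_registry()) {
  iss <- list(check_keys(instance, "instance", ""))
  add <- function(x) iss[[length(iss) + 1]] <<- x

  # form-level dates
  doc <- instance$date_of_completion
  doc_date <- NULL
  if (is.null(doc) || !cl_is_date_string(doc)) {
    add(issue("error", "BAD_DATE", "/date_of_completion",
              "date_of_completion must be a valid ISO calendar date"))
  } else {
    doc_date <- as.Date(doc)
  }

  # persons
  ids <- vapply(instance$persons, function(p) p$id %||% "", character(1))
  if (anyDuplicated(ids[nzchar(ids)])) {
    dup <- unique(ids[duplicated(ids)])
    add(issue("error", "DUPLICATE_ID", "/persons",
              paste("duplicate person id(s):", paste(dup, collapse = ", "))))
  }
  kinds <- character(0)
  for (i in seq_along(instance$persons)) {
    p <- instance$persons[[i]]
    path <- sprintf("/persons/%d", i)
    add(check_keys(p, "person", path))
    if (!is.null(p$contact)) add(check_keys(p$contact, "contact", paste0(path, "/contact")))
    if (!is.null(p$signature)) add(check_keys(p$signature, "signature", paste0(path, "/signature")))
    if (is.null(p$full_name) || !nzchar(p$full_name %||% "")) {
      add(issue("error", "MISSING_FIELD", paste0(path, "/full_name"),
                "person full_name is required"))
    }
    role <- p$role %||% NA_character_
    kind <- p$kind %||% NA_character_
    kinds <- c(kinds, kind)
    if (!role %in% PERSON_ROLES) {
      add(issue("error", "BAD_ENUM", paste0(path, "/role"),
                sprintf("unknown role '%s'", role)))
    } else if (!is.na(kind)) {
      professional <- role %in% PROFESSIONAL_ROLES
      if (professional != identical(kind, "professional")) {
        add(issue("error", "KIND_ROLE_MISMATCH", paste0(path, "/kind"),
                  sprintf("role '%s' implies kind '%s', found '%s'", role,
                          if (professional) "professional" else "non_professional",
                          kind)))
      }
    }
    sig_date <- p$signature$date
    if (!is.null(sig_date)) {
      if (!cl_is_date_string(sig_date)) {
        add(issue("error", "BAD_DATE", paste0(path, "/signature/date"),
                  "signature date must be a valid ISO calendar date"))
      } else if (!is.null(doc_date) && as.Date(sig_date) > doc_date) {
        add(issue("error", "DATE_ORDER", paste0(path, "/signature/date"),
                  sprintf("signature date %s follows date_of_completion %s",
                          sig_date, doc)))
      }
    }
    cobo <- p$consents_on_behalf_of
    if (!is.null(cobo)) {
      add(check_keys(cobo, "consents_on_behalf_of",
                     paste0(path, "/consents_on_behalf_of")))
      target <- cobo$person %||% NA_character_
      if (identical(target, p$id)) {
        add(issue("error", "SELF_PROXY", paste0(path, "/consents_on_behalf_of"),
                  "a person cannot consent on behalf of themselves"))
      } else if (!target %in% ids) {
        add(issue("error", "PROXY_TARGET_MISSING",
                  paste0(path, "/consents_on_behalf_of"),
                  sprintf("referenced person '%s' is not on this form", target)))
      }
    }
  }
  if (!any(kinds == "non_professional", na.rm = TRUE)) {
    add(issue("error", "NO_NON_PROFESSIONAL", "/persons",
              "at least one non-professional person must be present"))
  }

  # organizations
  for (i in seq_along(instance$organizations)) {
    o <- instance$organizations[[i]]
    path <- sprintf("/organizations/%d", i)
    add(check_keys(o, "organization", path))
    if (!is.null(o$subtype) && !o$subtype %in% ORG_SUBTYPES) {
      add(issue("error", "BAD_ENUM", paste0(path, "/subtype"),
                sprintf("unknown organization subtype '%s'", o$subtype)))
    }
  }

  # questions: ids unique, logic only references earlier questions
  qids <- vapply(instance$questions, function(q) q$id %||% "", character(1))
  if (anyDuplicated(qids[nzchar(qids)])) {
    add(issue("error", "DUPLICATE_ID", "/questions",
              paste("duplicate question id(s):",
                    paste(unique(qids[duplicated(qids)]), collapse = ", "))))
  }
  for (i in seq_along(instance$questions)) {
    q <- instance$questions[[i]]
    path <- sprintf("/questions/%d", i)
    add(check_keys(q, "question", path))
    if (!is.null(q$logic)) add(check_keys(q$logic, "logic", paste0(path, "/logic")))
    if (!is.null(q$responses)) {
      add(check_keys(q$responses, "question_responses", paste0(path, "/responses")))
    }
    if (!is.null(q$method_of_collection) &&
        !q$method_of_collection %in% COLLECTION_METHODS) {
      add(issue("error", "BAD_ENUM", paste0(path, "/method_of_collection"),
                sprintf("unknown method_of_collection '%s'", q$method_of_collection)))
    }
    if (!is.null(q$logic)) {
      ref <- q$logic$question %||% NA_character_
      earlier <- qids[seq_len(i - 1)]
      if (!ref %in% earlier) {
        add(issue("error", "LOGIC_ORDER", paste0(path, "/logic"),
                  sprintf("logic references '%s', which does not precede question '%s'",
                          ref, q$id %||% "?")))
      }
    }
  }

  # responses answer existing questions
  for (key in names(instance$responses)) {
    if (!key %in% qids) {
      add(issue("error", "DANGLING_RESPONSE", paste0("/responses/", key),
                sprintf("response key '%s' matches no question id", key)))
    }
  }

  # scopes
  for (i in seq_along(instance$scopes)) {
    s <- instance$scopes[[i]]
    path <- sprintf("/scopes/%d", i)
    add(check_keys(s, "scope", path))
    if (!is.null(s$biological_samples)) {
      add(check_keys(s$biological_samples, "biological_samples",
                     paste0(path, "/biological_samples")))
    }
    cat_ok <- (s$category %||% "") %in% RECORD_CATEGORIES
    if (!cat_ok) {
      add(issue("error", "BAD_ENUM", paste0(path, "/category"),
                sprintf("unknown record category '%s'", s$category %||% "")))
    }
    if (length(s$economic_parts %||% character(0)) > 0 &&
        !identical(s$category, "economic")) {
      add(issue("error", "SCOPE_PART_MISMATCH", paste0(path, "/economic_parts"),
                "economic_parts set on a non-economic scope"))
    }
    health_extras <- length(s$health_temporal %||% character(0)) > 0 ||
      length(s$health_parts %||% character(0)) > 0 ||
      !is.null(s$biological_samples)
    if (health_extras && !identical(s$category, "health")) {
      add(issue("error", "SCOPE_PART_MISMATCH", path,
                "health qualifiers set on a non-health scope"))
    }
    bad_econ <- setdiff(unlist(s$economic_parts), ECONOMIC_PARTS)
    bad_temp <- setdiff(unlist(s$health_temporal), HEALTH_TEMPORAL)
    bad_part <- setdiff(unlist(s$health_parts), HEALTH_PARTS)
    for (b in c(bad_econ, bad_temp, bad_part)) {
      add(issue("error", "BAD_ENUM", path,
                sprintf("unknown scope sub-part '%s'", b)))
    }
  }

  # general block and informational documents
  if (!is.null(instance$general)) {
    add(check_keys(instance$general, "general", "/general"))
  }
  for (i in seq_along(instance$informational_documents)) {
    d <- instance$informational_documents[[i]]
    path <- sprintf("/informational_documents/%d", i)
    add(check_keys(d, "informational_document", path))
    if (!is.null(d$study)) add(check_keys(d$study, "study", paste0(path, "/study")))
    if (is.null(d$type)) {
      add(issue("error", "MISSING_FIELD", paste0(path, "/type"),
                "informational document type is required"))
    } else if (!d$type %in% DOCUMENT_TYPES) {
      add(issue("error", "BAD_ENUM", paste0(path, "/type"),
                sprintf("unknown document type '%s'", d$type)))
    }
  }

  out <- do.call(rbind, iss)
  if (is.null(out) || nrow(out) == 0) return(no_issues())
  out <- out[order(out$path, out$code, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

validation_errors <- function(issues) {
  issues[issues$severity == "error", , drop = FALSE]
}

stop_invalid <- function(issues, action) {
  err <- validation_errors(issues)
  cond <- structure(
    class = c("consentlink_validation_error", "error", "condition"),
    list(message = sprintf("%s refused: %d validation error(s), e.g. [%s] %s",
                           action, nrow(err), err$code[1], err$message[1]),
         call = NULL, issues = issues)
  )
  stop(cond)
}

#' Validation issues attached to a validation error
#'
#' When [write_instance()] or [read_instance()] refuse a document, the error
#' they signal carries the full issue table; this helper extracts it.
#'
#' @param e a condition of class `consentlink_validation_error`
#' @return the issue data.frame, or `NULL` if the condition carries none
#' @export
condition_issues <- function(e) e$issues
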