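# Domain types for consent-form instances. Constructors build plain lists in
# a fixed canonical key order so that serialization is deterministic; the
# same order is re-imposed when documents are read back.

PROFESSIONAL_ROLES <- c("interviewer", "staff_member", "teacher",
                        "general_practitioner", "principal_investigator")
NON_PROFESSIONAL_ROLES <- c("interviewee", "consent_subject")
PERSON_ROLES <- c(NON_PROFESSIONAL_ROLES, PROFESSIONAL_ROLES)
PERSON_KINDS <- c("professional", "non_professional")
ORG_SUBTYPES <- c("generic", "academic_institution")
COLLECTION_METHODS <- c("self_completion", "interviewer_administered",
                        "online", "telephone")
RECORD_CATEGORIES <- c("economic", "education", "legal", "family",
                       "mobile_phone_usage", "health")
ECONOMIC_PARTS <- c("benefits_claims", "ni_contributions", "tax")
HEALTH_TEMPORAL <- c("past", "present", "future")
HEALTH_PARTS <- c("treatments_and_management", "tests_and_assessments",
                  "use_of_health_services", "rights_to_results")
DOCUMENT_TYPES <- c("information_sheet", "leaflet", "linkage_case_study", "other")
EVENT_TYPES <- c("consent_given", "consent_withdrawn", "assent_given",
                 "dissent", "reconsent", "future_contact_revoked")

match_enum <- function(value, choices, what) {
  if (is.null(value) || length(value) != 1 || !value %in% choices) {
    stop(sprintf("%s must be one of: %s (got %s)", what,
                 paste(choices, collapse = ", "),
                 deparse(value)), call. = FALSE)
  }
  value
}

#' Create a person record
#'
#' A person participating in the consent process: the interviewee, the person
#' consent is given for (if different), or professional staff such as an
#' interviewer. Professionals and non-professionals are distinguished by
#' `kind`, matching the model's specialization of the person element.
#'
#' @param id identifier unique within the form (e.g. `"p1"`)
#' @param full_name the person's printed name
#' @param role one of interviewee, consent_subject, interviewer, staff_member,
#'   teacher, general_practitioner, principal_investigator
#' @param kind `"professional"` or `"non_professional"`; defaults to the kind
#'   implied by `role`
#' @param contact list with optional `telephone`, `email`, `location`,
#'   `nationality`
#' @param date_of_birth optional ISO date; needed when an assent policy must
#'   compute the person's age
#' @param signature list with `signed` (logical) and optional `date`
#' @param confirmation_of_understanding logical
#' @param consents_on_behalf_of optional list with `person` (the id of the
#'   person consented for) and `relationship`
#' @return a list of class `cl_person`
#' @export
person <- function(id, full_name, role,
                   kind = NULL,
                   contact = list(),
                   date_of_birth = NULL,
                   signature = list(signed = FALSE, date = NULL),
                   confirmation_of_understanding = FALSE,
                   consents_on_behalf_of = NULL) {
  role <- match_enum(role, PERSON_ROLES, "role")
  implied <- if (role %in% PROFESSIONAL_ROLES) "professional" else "non_professional"
  kind <- if (is.null(kind)) implied else match_enum(kind, PERSON_KINDS, "kind")
  if (!is.null(signature$date)) cl_parse_date(signature$date, "signature date")
  if (!is.null(date_of_birth)) cl_parse_date(date_of_birth, "date of birth")
  structure(cl_compact(list(
    id = id,
    full_name = full_name,
    role = role,
    kind = kind,
    contact = cl_compact(list(
      telephone = contact$telephone,
      email = contact$email,
      location = contact$location,
      nationality = contact$nationality
    )),
    date_of_birth = date_of_birth,
    signature = cl_compact(list(
      signed = isTRUE(signature$signed),
      date = signature$date
    )),
    confirmation_of_understanding = isTRUE(confirmation_of_understanding),
    consents_on_behalf_of = if (!is.null(consents_on_behalf_of)) {
      list(person = consents_on_behalf_of$person,
           relationship = consents_on_behalf_of$relationship %||% "guardian")
    }
  )), class = "cl_person")
}

#' Create an organization record
#'
#' @param organization_name name of the organization
#' @param ethics_approval_reference ethics committee approval reference
#' @param subtype `"generic"` or `"academic_institution"`; an academic
#'   institution inherits both attributes from the organization element
#' @return a list of class `cl_organization`
#' @export
organization <- function(organization_name,
                         ethics_approval_reference = NULL,
                         subtype = "generic") {
  subtype <- match_enum(subtype, ORG_SUBTYPES, "subtype")
  structure(cl_compact(list(
    organization_name = organization_name,
    ethics_approval_reference = ethics_approval_reference,
    subtype = subtype
  )), class = "cl_organization")
}

#' Create a consent question or statement
#'
#' Questions are composites of logic, responses and purpose, and are part of
#' the form's data collection together with the method of collection.
#'
#' @param id question id, unique within the form
#' @param text the question or statement text
#' @param kind `"question"` or `"statement"`
#' @param logic optional branching rule: list with `question` (id of an
#'   earlier question) and `response` (value that makes this one applicable)
#' @param responses allowed responses: list with `type` (`"free_text"` or
#'   `"coded"`), and for coded lists `code_list` (its name) and `values`
#' @param purpose what the question establishes
#' @param method_of_collection one of self_completion,
#'   interviewer_administered, online, telephone
#' @return a list of class `cl_question`
#' @export
question <- function(id, text, kind = "question",
                     logic = NULL,
                     responses = list(type = "coded",
                                      code_list = "consent_yes_no",
                                      values = c("yes", "no")),
                     purpose = NULL,
                     method_of_collection = "self_completion") {
  kind <- match_enum(kind, c("question", "statement"), "kind")
  method_of_collection <- match_enum(method_of_collection, COLLECTION_METHODS,
                                     "method_of_collection")
  responses$type <- match_enum(responses$type, c("free_text", "coded"),
                               "responses$type")
  structure(cl_compact(list(
    id = id,
    text = text,
    kind = kind,
    logic = if (!is.null(logic)) list(question = logic$question,
                                      response = logic$response),
    responses = cl_compact(list(
      type = responses$type,
      code_list = responses$code_list,
      values = responses$values
    )),
    purpose = purpose,
    method_of_collection = method_of_collection
  )), class = "cl_question")
}

#' Create a record-linkage scope
#'
#' One consent decision about one category of personal records. The category
#' enum carries the model's six record types. Economic scopes may name the
#' composed sub-elements (benefits claims, NI contributions, tax); health
#' scopes may carry temporal qualifiers (past/present/future), named health
#' sub-parts, and a biological-samples block. An empty sub-part or temporal
#' set means the grant is unrestricted within the category.
#'
#' @param category one of economic, education, legal, family,
#'   mobile_phone_usage, health
#' @param granted logical: whether consent for this scope was given
#' @param economic_parts subset of benefits_claims, ni_contributions, tax
#' @param health_temporal subset of past, present, future
#' @param health_parts subset of treatments_and_management,
#'   tests_and_assessments, use_of_health_services, rights_to_results
#' @param biological_samples optional list with `type_of_test`,
#'   `storage_of_sample`, `lab_name`, `lab_site`
#' @param future_contact logical: consent to be contacted again
#' @param detail optional free-text detail for leaf categories
#' @return a list of class `cl_record_scope`
#' @export
record_scope <- function(category, granted = TRUE,
                         economic_parts = character(0),
                         health_temporal = character(0),
                         health_parts = character(0),
                         biological_samples = NULL,
                         future_contact = FALSE,
                         detail = NULL) {
  category <- match_enum(category, RECORD_CATEGORIES, "category")
  economic_parts <- as.character(economic_parts)
  health_temporal <- as.character(health_temporal)
  health_parts <- as.character(health_parts)
  stopifnot(all(economic_parts %in% ECONOMIC_PARTS),
            all(health_temporal %in% HEALTH_TEMPORAL),
            all(health_parts %in% HEALTH_PARTS))
  if (length(economic_parts) > 0 && category != "economic") {
    stop("economic_parts may only be set when category is 'economic'",
         call. = FALSE)
  }
  if ((length(health_temporal) > 0 || length(health_parts) > 0 ||
       !is.null(biological_samples)) && category != "health") {
    stop("health qualifiers may only be set when category is 'health'",
         call. = FALSE)
  }
  structure(cl_compact(list(
    category = category,
    granted = isTRUE(granted),
    economic_parts = if (length(economic_parts)) economic_parts,
    health_temporal = if (length(health_temporal)) health_temporal,
    health_parts = if (length(health_parts)) health_parts,
    biological_samples = if (!is.null(biological_samples)) cl_compact(list(
      type_of_test = biological_samples$type_of_test,
      storage_of_sample = biological_samples$storage_of_sample,
      lab_name = biological_samples$lab_name,
      lab_site = biological_samples$lab_site
    )),
    future_contact = isTRUE(future_contact),
    detail = detail
  )), class = "cl_record_scope")
}

#' Create an informational document record
#'
#' Material accompanying a consent form: information sheets, leaflets, or
#' linkage case studies. Carries the study description (aims, contact
#' details, funding bodies, objectives, reviewers), the research description
#' of what information may be accessed, and the withdrawal procedure.
#'
#' @param type one of information_sheet, leaflet, linkage_case_study, other
#' @param accessibility how the document is made accessible
#' @param audience intended audience
#' @param study list with `aims`, `contact_details`, `funding_bodies`
#'   (character vector, possibly empty), `objectives`, `reviewers`
#' @param research description of the information that may be accessed
#' @param withdrawal_procedure how to withdraw consent
#' @param data_flow_description optional description of how linked data flows
#' @return a list of class `cl_infodoc`
#' @export
informational_document <- function(type,
                                   accessibility = "online",
                                   audience = "participants",
                                   study = list(),
                                   research = NULL,
                                   withdrawal_procedure = NULL,
                                   data_flow_description = NULL) {
  type <- match_enum(type, DOCUMENT_TYPES, "type")
  structure(cl_compact(list(
    accessibility = accessibility,
    audience = audience,
    type = type,
    study = list(
      aims = study$aims %||% NULL,
      contact_details = study$contact_details %||% NULL,
      funding_bodies = as.character(study$funding_bodies %||% character(0)),
      objectives = study$objectives %||% NULL,
      reviewers = study$reviewers %||% NULL
    ),
    research = research,
    withdrawal_procedure = withdrawal_procedure,
    data_flow_description = data_flow_description
  )), class = "cl_infodoc")
}

#' Create a consent-form instance
#'
#' One completed consent form, following the common flow observed across
#' longitudinal-study forms: demographic details, questions/statements of
#' consent, then confirmation through signing, dating and printing of name.
#' The date of completion belongs to the form itself.
#'
#' @param form_id form identifier
#' @param study_name study the form belongs to
#' @param organizations list of [organization()] records
#' @param persons list of [person()] records; at least one non-professional
#' @param questions ordered list of [question()] records
#' @param responses named list mapping question id to the recorded response
#' @param scopes list of [record_scope()] records
#' @param date_of_completion ISO date the form was completed
#' @param general list with optional `aim`, `undertakings`,
#'   `confirmatory_information`
#' @param instructions_for_next_steps what to do with the completed form
#' @param informational_documents list of [informational_document()] records
#' @param extensions free-form named list for forward-compatible extension
#'   content; the only place unregistered keys are allowed
#' @return a list of class `cl_instance`
#' @export
consent_form_instance <- function(form_id, study_name,
                                  organizations = list(),
                                  persons = list(),
                                  questions = list(),
                                  responses = list(),
                                  scopes = list(),
                                  date_of_completion,
                                  general = list(),
                                  instructions_for_next_steps = NULL,
                                  informational_documents = list(),
                                  extensions = list()) {
  cl_parse_date(date_of_completion, "date_of_completion")
  structure(list(
    form_id = form_id,
    study_name = study_name,
    organizations = unname(organizations),
    persons = unname(persons),
    questions = unname(questions),
    responses = responses,
    scopes = unname(scopes),
    date_of_completion = date_of_completion,
    general = cl_compact(list(
      aim = general$aim,
      undertakings = general$undertakings,
      confirmatory_information = general$confirmatory_information
    )),
    instructions_for_next_steps = instructions_for_next_steps,
    informational_documents = unname(informational_documents),
    extensions = extensions
  ), class = "cl_instance")
}

#' Create a consent lifecycle event
#'
#' A dated change in consent state: consent given or withdrawn, assent or
#' dissent by a maturing subject, re-consent, or revocation of future
#' contact. Events are the unit the permission engine replays.
#'
#' @param event_type one of consent_given, consent_withdrawn, assent_given,
#'   dissent, reconsent, future_contact_revoked
#' @param date ISO date of the event
#' @param form_id instance the event attaches to
#' @param person_id id of the person the event concerns within that instance
#' @param target_scope optional scope selector: list with `category` and
#'   optional `part` and `temporal`; absent means the whole form
#' @return a list of class `cl_event`
#' @export
lifecycle_event <- function(event_type, date, form_id, person_id,
                            target_scope = NULL) {
  event_type <- match_enum(event_type, EVENT_TYPES, "event_type")
  cl_parse_date(date, "event date")
  if (!is.null(target_scope)) {
    target_scope$category <- match_enum(
      target_scope$category, c(RECORD_CATEGORIES, "future_contact"), "category")
  }
  structure(cl_compact(list(
    event_type = event_type,
    date = date,
    actor = list(form_id = form_id, person_id = person_id),
    target_scope = if (!is.null(target_scope)) cl_compact(list(
      category = target_scope$category,
      part = target_scope$part,
      temporal = target_scope$temporal
    ))
  )), class = "cl_event")
}

#' @export
print.cl_instance <- function(x, ...) {
  cat(sprintf("<consent form %s> study: %s, completed %s\n",
              x$form_id, x$study_name, x$date_of_completion))
  cat(sprintf("  %d person(s), %d question(s)/statement(s), %d scope(s), %d document(s)\n",
              length(x$persons), length(x$questions), length(x$scopes),
              length(x$informational_documents)))
  invisible(x)
}
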