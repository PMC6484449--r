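# Seeded synthetic consent-form generator.
#
# Profiles emulate the structural patterns of three longitudinal-study
# consent forms: an ELSA-like form (interviewer-administered, with
# instructions on what to do with the completed copies), a CLSA-like form
# (three consent statements), and an LSAC-like form (a child subject with a
# guardian consenting on their behalf, introductory aim/undertakings, and an
# accompanying information sheet). Names and places come from an
# obviously-fictitious packaged wordlist: no realistic personal data is ever
# generated.

#' Study profile for the fixture generator
#'
#' @param name `"elsa_like"`, `"clsa_like"`, `"lsac_like"`, or `"generic"`
#' @param ... feature overrides: `interviewer_administered`,
#'   `instructions_for_next_steps`, `n_statements`, `professional_signatory`,
#'   `child_subject_with_proxy`, `introductory_aim_and_undertakings`,
#'   `informational_document_present`
#' @return a list of class `cl_profile`
#' @export
study_profile <- function(name = c("generic", "elsa_like", "clsa_like",
                                   "lsac_like"), ...) {
  name <- match.arg(name)
  features <- switch(name,
    elsa_like = list(interviewer_administered = TRUE,
                     instructions_for_next_steps = TRUE,
                     n_statements = 2L,
                     professional_signatory = TRUE,
                     child_subject_with_proxy = FALSE,
                     introductory_aim_and_undertakings = FALSE,
                     informational_document_present = FALSE),
    clsa_like = list(interviewer_administered = TRUE,
                     instructions_for_next_steps = FALSE,
                     n_statements = 3L,
                     professional_signatory = TRUE,
                     child_subject_with_proxy = FALSE,
                     introductory_aim_and_undertakings = FALSE,
                     informational_document_present = FALSE),
    lsac_like = list(interviewer_administered = FALSE,
                     instructions_for_next_steps = FALSE,
                     n_statements = 2L,
                     professional_signatory = FALSE,
                     child_subject_with_proxy = TRUE,
                     introductory_aim_and_undertakings = TRUE,
                     informational_document_present = TRUE),
    generic = list(interviewer_administered = FALSE,
                   instructions_for_next_steps = FALSE,
                   n_statements = 1L,
                   professional_signatory = FALSE,
                   child_subject_with_proxy = FALSE,
                   introductory_aim_and_undertakings = FALSE,
                   informational_document_present = FALSE)
  )
  overrides <- list(...)
  stopifnot(all(names(overrides) %in% names(features)))
  features[names(overrides)] <- overrides
  if (features$n_statements < 1) {
    stop("n_statements must be at least 1", call. = FALSE)
  }
  if (name == "lsac_like" && !isTRUE(features$child_subject_with_proxy)) {
    stop("an lsac_like profile implies a child subject with proxy consent",
         call. = FALSE)
  }
  structure(c(list(name = name), list(features = features)),
            class = "cl_profile")
}

cl_wordlist <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lines <- readLines(cl_extdata("wordlist.txt"), encoding = "UTF-8")
      lines <- lines[!grepl("^#", lines) & nzchar(lines)]
      kv <- strsplit(lines, " ", fixed = TRUE)
      kinds <- vapply(kv, `[[`, character(1), 1)
      words <- vapply(kv, `[[`, character(1), 2)
      cache <<- split(words, kinds)
    }
    cache
  }
})

fake_name <- function(wl) {
  paste(sample(wl$given, 1), sample(wl$family, 1))
}

#' Generate a synthetic consent-form instance
#'
#' Instances follow the flow common to longitudinal-study consent forms:
#' demographic details, then questions/statements of consent, then
#' confirmation through signing and dating. Generation is deterministic for
#' a given profile and seed, uses its own seeded generator without touching
#' the caller's RNG state, and always yields an instance that validates with
#' zero errors against the default registry.
#'
#' @param profile a [study_profile()]
#' @param seed integer seed
#' @return a `cl_instance`
#' @examples
#' inst <- generate_instance(study_profile("clsa_like"), seed = 1)
#' length(inst$questions)
#' @export
generate_instance <- function(profile = study_profile("generic"), seed = 1) {
  stopifnot(inherits(profile, "cl_profile"))
  with_local_seed(seed, {
    wl <- cl_wordlist()
    f <- profile$features
    completion <- as.Date("2015-01-01") + sample.int(730, 1) - 1
    completion_s <- cl_format_date(completion)
    form_id <- sprintf("%s-%05d", toupper(substr(profile$name, 1, 4)),
                       sample.int(99999L, 1))
    study_name <- sprintf("%s Synthetic Cohort", sample(wl$place, 1))

    persons <- list()
    if (f$child_subject_with_proxy) {
      child_dob <- completion - round(runif(1, 6, 10) * 365.25)
      persons <- c(persons, list(
        person("p1", fake_name(wl), "interviewee",
               contact = list(telephone = sprintf("+00 %07d", sample.int(9999999L, 1)),
                              email = sprintf("guardian%d@example.invalid", sample.int(999L, 1)),
                              location = sample(wl$place, 1),
                              nationality = sample(wl$nation, 1)),
               signature = list(signed = TRUE, date = completion_s),
               confirmation_of_understanding = TRUE,
               consents_on_behalf_of = list(person = "p2",
                                            relationship = "parent")),
        person("p2", fake_name(wl), "consent_subject",
               date_of_birth = cl_format_date(child_dob),
               signature = list(signed = FALSE))
      ))
    } else {
      persons <- c(persons, list(
        person("p1", fake_name(wl), "interviewee",
               contact = list(telephone = sprintf("+00 %07d", sample.int(9999999L, 1)),
                              email = sprintf("subject%d@example.invalid", sample.int(999L, 1)),
                              location = sample(wl$place, 1),
                              nationality = sample(wl$nation, 1)),
               date_of_birth = cl_format_date(completion - round(runif(1, 25, 80) * 365.25)),
               signature = list(signed = TRUE, date = completion_s),
               confirmation_of_understanding = TRUE)
      ))
    }
    if (f$professional_signatory) {
      persons <- c(persons, list(
        person(sprintf("p%d", length(persons) + 1), fake_name(wl),
               "interviewer",
               signature = list(signed = TRUE, date = completion_s))
      ))
    }

    method <- if (f$interviewer_administered) "interviewer_administered" else "self_completion"
    statement_texts <- c(
      "I agree that my study records may be linked to my health records.",
      "I agree that my study records may be linked to my economic records.",
      "I agree that the study may hold my contact details for future contact.",
      "I agree that linked data may be shared with approved researchers.",
      "I agree that my records may be used for follow-up studies."
    )
    n <- f$n_statements
    questions <- lapply(seq_len(n), function(i) {
      question(sprintf("q%d", i),
               statement_texts[((i - 1) %% length(statement_texts)) + 1],
               kind = "statement",
               logic = if (i == n && n >= 2) list(question = "q1", response = "yes"),
               purpose = "establish consent for record linkage",
               method_of_collection = method)
    })
    responses <- setNames(as.list(rep("yes", n)),
                          vapply(questions, `[[`, character(1), "id"))

    scopes <- list(
      record_scope("health", granted = TRUE,
                   health_temporal = if (profile$name == "elsa_like") "past" else character(0),
                   future_contact = TRUE)
    )
    if (profile$name == "elsa_like") {
      scopes <- c(scopes, list(
        record_scope("economic", granted = TRUE,
                     economic_parts = c("benefits_claims", "ni_contributions", "tax"))
      ))
    }

    docs <- if (f$informational_document_present) {
      list(informational_document(
        type = "information_sheet",
        accessibility = "online and on paper",
        audience = "participants and guardians",
        study = list(
          aims = "Describe the life course of a synthetic cohort.",
          contact_details = sprintf("office%d@example.invalid", sample.int(99L, 1)),
          funding_bodies = c("Synthetic Research Council"),
          objectives = "Link study records to routine records.",
          reviewers = "Synthetic Ethics Committee"
        ),
        research = "Health and economic records held by public bodies may be accessed.",
        withdrawal_procedure = "Write to the study office to withdraw at any time.",
        data_flow_description = "Identifiers flow to the trusted third party only."
      ))
    } else list()

    consent_form_instance(
      form_id = form_id,
      study_name = study_name,
      organizations = list(organization(
        sprintf("University of %s", sample(wl$place, 1)),
        ethics_approval_reference = sprintf("REC-%04d", sample.int(9999L, 1)),
        subtype = "academic_institution")),
      persons = persons,
      questions = questions,
      responses = responses,
      scopes = scopes,
      date_of_completion = completion_s,
      general = if (f$introductory_aim_and_undertakings) {
        list(aim = "This study follows children and their families over time.",
             undertakings = "The study will keep your information secure.",
             confirmatory_information = "You may keep a copy of this form.")
      } else list(),
      instructions_for_next_steps = if (f$instructions_for_next_steps) {
        "Keep one copy; return the other copy to the study office."
      },
      informational_documents = docs
    )
  })
}

#' Generate a synthetic population of consent instances
#'
#' Builds a store of `n` independent instances. A fraction `proxy_rate` are
#' child-subject forms with guardian proxy consent; a fraction
#' `withdrawal_rate` carry a whole-form consent-withdrawn event dated after
#' completion. Deterministic per seed.
#'
#' @param n number of instances (>= 0)
#' @param withdrawal_rate probability an instance later withdraws
#' @param proxy_rate probability an instance is a proxy-consent form
#' @param seed integer seed
#' @return a `cl_store`
#' @examples
#' store <- generate_population(5, withdrawal_rate = 0.2, proxy_rate = 0, seed = 7)
#' store
#' @export
generate_population <- function(n, withdrawal_rate = 0, proxy_rate = 0,
                                seed = 1) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 0)
  if (!is.numeric(withdrawal_rate) || withdrawal_rate < 0 || withdrawal_rate > 1) {
    stop("withdrawal_rate must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(proxy_rate) || proxy_rate < 0 || proxy_rate > 1) {
    stop("proxy_rate must be in [0, 1]", call. = FALSE)
  }
  n <- as.integer(n)
  plan <- with_local_seed(seed, {
    list(proxy = runif(n) < proxy_rate,
         withdraw = runif(n) < withdrawal_rate,
         delay = sample.int(365L, max(n, 1), replace = TRUE),
         seeds = sample.int(.Machine$integer.max - 1L, max(n, 1)))
  })
  instances <- vector("list", n)
  for (i in seq_len(n)) {
    prof <- if (plan$proxy[i]) study_profile("lsac_like") else study_profile("generic")
    inst <- generate_instance(prof, seed = plan$seeds[i])
    inst$form_id <- sprintf("POP-%05d", i) # unique ids regardless of seed collisions
    instances[[i]] <- inst
  }
  store <- consent_store(instances, validate = FALSE)
  for (i in seq_len(n)) {
    if (plan$withdraw[i]) {
      inst <- instances[[i]]
      subject <- if (plan$proxy[i]) "p2" else "p1"
      store <- apply_event(store, lifecycle_event(
        "consent_withdrawn",
        cl_format_date(as.Date(inst$date_of_completion) + plan$delay[i]),
        inst$form_id, subject))
    }
  }
  store
}
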