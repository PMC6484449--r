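# Linkage-permission resolution over consent instances and lifecycle events.
#
# Semantics, in order of application:
#   * default-deny: absence of consent is denial, never "unknown";
#   * each granted scope of an instance acts as a consent_given entry dated
#     at the form's date of completion, attached to the consent subject
#     (directly, or through a guardian's consents_on_behalf_of link);
#   * lifecycle events are replayed chronologically with last-event-wins
#     per scope selector; withdrawing a broader scope revokes every
#     narrower scope inside it;
#   * contradictory events on the same calendar day are unresolvable
#     (forms carry dates, not times) and yield "unknown";
#   * under the guardian_expires_at_age policy, proxy consent lapses once
#     the subject reaches the assent age with no assent event on record,
#     leaving a genuine gap: "unknown".
#
# Scopes are resolved on an atom lattice: every selector expands to the set
# of (category, sub-part, temporal) atoms beneath it; a query is permitted
# only if every atom under its selector is in the granted state.

#' Assent policy for maturing consent subjects
#'
#' Proxy consent (a guardian consenting on behalf of a child) weakens as the
#' subject matures. The mechanics are pluggable because studies differ:
#' either the guardian's consent persists until the subject's own assent or
#' dissent event, or it expires outright once the subject reaches the assent
#' age, leaving an "unknown" gap until an assent event is recorded.
#'
#' @param assent_required_from_age age in whole years from which the
#'   subject's own assent is expected; `NULL` disables age handling
#' @param behaviour `"guardian_persists_until_assent_event"` (default) or
#'   `"guardian_expires_at_age"`
#' @return a list of class `cl_assent_policy`
#' @export
assent_policy <- function(assent_required_from_age = NULL,
                          behaviour = c("guardian_persists_until_assent_event",
                                        "guardian_expires_at_age")) {
  behaviour <- match.arg(behaviour)
  if (!is.null(assent_required_from_age)) {
    stopifnot(is.numeric(assent_required_from_age),
              length(assent_required_from_age) == 1,
              assent_required_from_age > 0)
  }
  structure(list(assent_required_from_age = assent_required_from_age,
                 behaviour = behaviour),
            class = "cl_assent_policy")
}

#' Create a store of consent instances and lifecycle events
#'
#' @param instances list of [consent_form_instance()]s
#' @param registry registry the instances are validated against
#' @param validate validate member instances on construction
#' @return a list of class `cl_store` with `instances` and `events`
#' @export
consent_store <- function(instances = list(),
                          registry = build_default_registry(),
                          validate = TRUE) {
  instances <- unname(instances)
  if (validate) {
    for (inst in instances) {
      issues <- validate_instance(inst, registry)
      if (nrow(validation_errors(issues)) > 0) {
        stop_invalid(issues, paste0("store construction (form ",
                                    inst$form_id, ")"))
      }
    }
  }
  ids <- vapply(instances, `[[`, character(1), "form_id")
  if (anyDuplicated(ids)) {
    stop("duplicate form_id in store: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(instances = instances, events = list()), class = "cl_store")
}

#' @export
print.cl_store <- function(x, ...) {
  cat(sprintf("<consent store> %d instance(s), %d lifecycle event(s)\n",
              length(x$instances), length(x$events)))
  invisible(x)
}

store_instance <- function(store, form_id) {
  for (inst in store$instances) if (identical(inst$form_id, form_id)) return(inst)
  NULL
}

store_person <- function(instance, person_id) {
  for (p in instance$persons) if (identical(p$id, person_id)) return(p)
  NULL
}

#' Append a lifecycle event to a store
#'
#' Value semantics: the returned store carries the event; the original store
#' is unmodified. Events referencing an unknown instance or person are
#' rejected.
#'
#' @param store a [consent_store()]
#' @param event a [lifecycle_event()]
#' @return a new `cl_store`
#' @export
apply_event <- function(store, event) {
  stopifnot(inherits(store, "cl_store"), inherits(event, "cl_event"))
  inst <- store_instance(store, event$actor$form_id)
  if (is.null(inst)) {
    stop("event references unknown instance: ", event$actor$form_id,
         call. = FALSE)
  }
  if (is.null(store_person(inst, event$actor$person_id))) {
    stop("event references unknown person: ", event$actor$person_id,
         " in form ", event$actor$form_id, call. = FALSE)
  }
  store$events <- c(store$events, list(event))
  store
}

#' Events of a store in chronological order
#' @param store a [consent_store()]
#' @return list of events sorted by date (stable for ties)
#' @export
store_events <- function(store) {
  if (length(store$events) == 0) return(list())
  dates <- as.Date(vapply(store$events, `[[`, character(1), "date"))
  store$events[order(dates)]
}

# --- atom lattice ---------------------------------------------------------

atom_parts <- function(category) {
  switch(category,
         economic = ECONOMIC_PARTS,
         health = HEALTH_PARTS,
         "")
}

atom_temporals <- function(category) {
  if (identical(category, "health")) HEALTH_TEMPORAL else ""
}

atoms_under <- function(category, part = NULL, temporal = NULL) {
  if (identical(category, "future_contact")) return("future_contact||")
  parts <- if (is.null(part)) atom_parts(category) else part
  temporals <- if (is.null(temporal)) atom_temporals(category) else temporal
  bad_part <- setdiff(parts, c(atom_parts(category), ""))
  if (length(bad_part) > 0) {
    stop("unknown sub-part for category ", category, ": ",
         paste(bad_part, collapse = ", "), call. = FALSE)
  }
  bad_t <- setdiff(temporals, c(atom_temporals(category), ""))
  if (length(bad_t) > 0) {
    stop("unknown temporal qualifier for category ", category, ": ",
         paste(bad_t, collapse = ", "), call. = FALSE)
  }
  as.vector(outer(parts, temporals,
                  function(p, t) paste(category, p, t, sep = "|")))
}

atom_universe <- function() {
  unlist(lapply(c(RECORD_CATEGORIES, "future_contact"), atoms_under),
         use.names = FALSE)
}

scope_atoms <- function(scope) {
  cat <- scope$category
  if (identical(cat, "economic")) {
    parts <- scope$economic_parts %||% character(0)
    atoms_under(cat, part = if (length(parts)) parts else NULL)
  } else if (identical(cat, "health")) {
    parts <- scope$health_parts %||% character(0)
    temporal <- scope$health_temporal %||% character(0)
    atoms_under(cat,
                part = if (length(parts)) parts else NULL,
                temporal = if (length(temporal)) temporal else NULL)
  } else {
    atoms_under(cat)
  }
}

event_atoms <- function(event) {
  ts <- event$target_scope
  if (identical(event$event_type, "future_contact_revoked")) {
    return(atoms_under("future_contact"))
  }
  if (is.null(ts)) return(atom_universe())
  atoms_under(ts$category, part = ts$part, temporal = ts$temporal)
}

# --- entry table ----------------------------------------------------------

# One row per (atom, dated grant/deny entry) affecting one person; the
# replay works entirely from this table.
store_entries <- function(store) {
  rows <- list()
  add <- function(person_key, atoms, date, type, proxy, ref) {
    if (length(atoms) == 0) return(invisible())
    rows[[length(rows) + 1]] <<- data.frame(
      person = person_key, atom = atoms, date = as.Date(date), type = type,
      proxy = proxy, ref = ref, stringsAsFactors = FALSE)
  }
  for (inst in store$instances) {
    proxies <- list() # subject id -> guardian id
    for (p in inst$persons) {
      if (!is.null(p$consents_on_behalf_of)) {
        proxies[[p$consents_on_behalf_of$person]] <- p$id
      }
    }
    subjects <- Filter(function(p) identical(p$role, "consent_subject"),
                       inst$persons)
    if (length(subjects) == 0) {
      subjects <- Filter(function(p) identical(p$kind, "non_professional"),
                         inst$persons)
    }
    for (sub in subjects) {
      key <- paste0(inst$form_id, ":", sub$id)
      via_proxy <- !is.null(proxies[[sub$id]])
      for (i in seq_along(inst$scopes)) {
        s <- inst$scopes[[i]]
        ref <- sprintf("%s/scopes/%d", inst$form_id, i)
        add(key, scope_atoms(s), inst$date_of_completion,
            if (isTRUE(s$granted)) "grant" else "deny", via_proxy, ref)
        if (isTRUE(s$future_contact)) {
          add(key, atoms_under("future_contact"), inst$date_of_completion,
              "grant", via_proxy, ref)
        }
      }
    }
  }
  events <- store$events
  for (i in seq_along(events)) {
    e <- events[[i]]
    key <- paste0(e$actor$form_id, ":", e$actor$person_id)
    ref <- sprintf("event/%d:%s@%s", i, e$event_type, e$date)
    type <- switch(e$event_type,
                   consent_given = "grant", reconsent = "grant",
                   assent_given = "assent",
                   consent_withdrawn = "deny", dissent = "deny",
                   future_contact_revoked = "deny")
    if (identical(type, "assent")) {
      rows[[length(rows) + 1]] <- data.frame(
        person = key, atom = "", date = as.Date(e$date), type = "assent",
        proxy = FALSE, ref = ref, stringsAsFactors = FALSE)
    } else {
      add(key, event_atoms(e), e$date, type, FALSE, ref)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(person = character(0), atom = character(0),
                      date = as.Date(character(0)), type = character(0),
                      proxy = logical(0), ref = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

person_key <- function(person) {
  if (is.character(person) && length(person) == 1) return(person)
  if (is.list(person)) return(paste0(person$form_id, ":", person$person_id))
  stop("person must be a \"form_id:person_id\" string or a list with form_id and person_id",
       call. = FALSE)
}

resolve_person <- function(store, key) {
  parts <- strsplit(key, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) return(NULL)
  inst <- store_instance(store, parts[1])
  if (is.null(inst)) return(NULL)
  store_person(inst, parts[2])
}

# --- resolution -----------------------------------------------------------

decision <- function(verdict, justification) {
  just <- if (length(justification) == 0) {
    data.frame(ref = character(0), rule = character(0), stringsAsFactors = FALSE)
  } else {
    unique(do.call(rbind, justification))
  }
  rownames(just) <- NULL
  structure(list(verdict = verdict, justification = just),
            class = "cl_decision")
}

#' @export
print.cl_decision <- function(x, ...) {
  cat("verdict:", x$verdict, "\n")
  if (nrow(x$justification) > 0) {
    for (i in seq_len(nrow(x$justification))) {
      cat(sprintf("  - [%s] %s\n", x$justification$rule[i],
                  x$justification$ref[i]))
    }
  }
  invisible(x)
}

#' Is record linkage permitted for a person?
#'
#' Answers a linkage query for one person, record category (or the
#' `future_contact` pseudo-category), optional sub-part/temporal selector,
#' and query date, replaying the store's consent history under the given
#' assent policy. The decision carries a justification trail naming the
#' scopes and events that determined it.
#'
#' @param store a [consent_store()]
#' @param person `"form_id:person_id"` reference (or list with those fields)
#' @param category one of the six record categories or `"future_contact"`
#' @param subscope optional list with `part` and/or `temporal` narrowing the
#'   query (e.g. `list(part = "tests_and_assessments", temporal = "past")`)
#' @param query_date ISO date of the query
#' @param policy an [assent_policy()]
#' @return a `cl_decision`: `verdict` one of permitted/denied/unknown plus a
#'   `justification` data.frame with columns `ref` and `rule`
#' @examples
#' store <- generate_population(3, withdrawal_rate = 0, proxy_rate = 0, seed = 1)
#' key <- eligible_cohort(store, "health", "2020-01-01")[1]
#' is_linkage_permitted(store, key, "health", query_date = "2020-01-01")
#' @export
is_linkage_permitted <- function(store, person, category,
                                 subscope = NULL,
                                 query_date,
                                 policy = assent_policy()) {
  stopifnot(inherits(store, "cl_store"))
  cl_parse_date(query_date, "query_date")
  category <- match_enum(category, c(RECORD_CATEGORIES, "future_contact"),
                         "category")
  key <- person_key(person)
  if (length(store$instances) == 0) {
    return(decision("denied", list(
      data.frame(ref = NA_character_, rule = "default_deny",
                 stringsAsFactors = FALSE))))
  }
  target <- resolve_person(store, key)
  if (is.null(target)) {
    stop("person not found in store: ", key, call. = FALSE)
  }
  entries <- store_entries(store)
  resolve_query(entries, key, category, subscope, query_date, policy, target)
}

resolve_query <- function(entries, key, category, subscope, query_date,
                          policy, target_person) {
  qd <- as.Date(query_date)
  atoms <- atoms_under(category,
                       part = subscope$part %||% NULL,
                       temporal = subscope$temporal %||% NULL)
  mine <- entries[entries$person == key & entries$date <= qd, , drop = FALSE]
  assent_seen <- any(mine$type == "assent")
  just <- list()
  states <- character(length(atoms))
  for (i in seq_along(atoms)) {
    a <- atoms[i]
    ea <- mine[mine$atom == a, , drop = FALSE]
    if (nrow(ea) == 0) {
      states[i] <- "none"
      next
    }
    last_date <- max(ea$date)
    last <- ea[ea$date == last_date, , drop = FALSE]
    types <- unique(last$type)
    if (all(c("grant", "deny") %in% types)) {
      states[i] <- "conflict"
      just[[length(just) + 1]] <- data.frame(
        ref = last$ref, rule = "same_day_conflict", stringsAsFactors = FALSE)
      next
    }
    if ("deny" %in% types) {
      states[i] <- "denied"
      just[[length(just) + 1]] <- data.frame(
        ref = last$ref[last$type == "deny"], rule = "withdrawal",
        stringsAsFactors = FALSE)
      next
    }
    # granted; check proxy validity under the policy
    grant_rows <- last[last$type == "grant", , drop = FALSE]
    if (all(grant_rows$proxy) &&
        identical(policy$behaviour, "guardian_expires_at_age") &&
        !is.null(policy$assent_required_from_age) && !assent_seen) {
      dob <- target_person$date_of_birth
      if (is.null(dob) ||
          cl_age_years(dob, qd) >= policy$assent_required_from_age) {
        states[i] <- "proxy_expired"
        just[[length(just) + 1]] <- data.frame(
          ref = grant_rows$ref, rule = "proxy_expired_without_assent",
          stringsAsFactors = FALSE)
        next
      }
    }
    states[i] <- "granted"
    just[[length(just) + 1]] <- data.frame(
      ref = grant_rows$ref, rule = if (any(grant_rows$proxy)) "proxy_grant" else "grant",
      stringsAsFactors = FALSE)
  }
  if (all(states == "granted")) return(decision("permitted", just))
  if (any(states %in% c("conflict", "proxy_expired"))) {
    return(decision("unknown", just))
  }
  if (all(states == "none")) {
    just <- list(data.frame(ref = NA_character_, rule = "default_deny",
                            stringsAsFactors = FALSE))
  }
  decision("denied", just)
}

#' Persons permitted linkage for a category at a date
#'
#' Batch form of [is_linkage_permitted()]: returns exactly the persons whose
#' verdict is `permitted`, as sorted `"form_id:person_id"` references.
#'
#' @inheritParams is_linkage_permitted
#' @return character vector of person references, sorted
#' @export
eligible_cohort <- function(store, category, query_date,
                            policy = assent_policy()) {
  stopifnot(inherits(store, "cl_store"))
  if (length(store$instances) == 0) return(character(0))
  entries <- store_entries(store)
  keys <- character(0)
  for (inst in store$instances) {
    for (p in inst$persons) {
      key <- paste0(inst$form_id, ":", p$id)
      d <- resolve_query(entries, key, category, NULL, query_date,
                         policy, p)
      if (identical(d$verdict, "permitted")) keys <- c(keys, key)
    }
  }
  sort(keys, method = "radix")
}
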