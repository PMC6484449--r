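# Independent chronological-replay oracle for linkage permission.
#
# Deliberately naive: enumerates every (category, part, temporal) atom with
# its own tables, collects every dated grant/deny touching each atom, and
# walks the day groups in order. Shares no code with the engine.

ORACLE_PARTS <- list(
  economic = c("benefits_claims", "ni_contributions", "tax"),
  health = c("treatments_and_management", "tests_and_assessments",
             "use_of_health_services", "rights_to_results"),
  education = "", legal = "", family = "", mobile_phone_usage = "",
  future_contact = ""
)
ORACLE_TEMPORAL <- list(health = c("past", "present", "future"))

oracle_atoms <- function(category, part = NULL, temporal = NULL) {
  parts <- if (is.null(part)) ORACLE_PARTS[[category]] else part
  temps <- if (!is.null(temporal)) temporal
           else if (category == "health") ORACLE_TEMPORAL$health else ""
  out <- character(0)
  for (p in parts) for (t in temps) out <- c(out, paste(category, p, t, sep = "|"))
  out
}

oracle_all_atoms <- function() {
  out <- character(0)
  for (cat in names(ORACLE_PARTS)) out <- c(out, oracle_atoms(cat))
  out
}

# every dated entry touching one person, as a plain data.frame
oracle_entries <- function(store, key) {
  out <- data.frame(date = as.Date(character(0)), type = character(0),
                    atom = character(0), proxy = logical(0),
                    stringsAsFactors = FALSE)
  push <- function(date, type, atoms, proxy) {
    if (length(atoms) == 0) return()
    out <<- rbind(out, data.frame(date = as.Date(date), type = type,
                                  atom = atoms, proxy = proxy,
                                  stringsAsFactors = FALSE))
  }
  for (inst in store$instances) {
    guardians_of <- list()
    for (p in inst$persons) {
      c_obo <- p$consents_on_behalf_of
      if (!is.null(c_obo)) guardians_of[[c_obo$person]] <- p$id
    }
    subjects <- character(0)
    for (p in inst$persons) if (identical(p$role, "consent_subject")) subjects <- c(subjects, p$id)
    if (length(subjects) == 0) {
      for (p in inst$persons) if (identical(p$kind, "non_professional")) subjects <- c(subjects, p$id)
    }
    for (sid in subjects) {
      if (!identical(paste0(inst$form_id, ":", sid), key)) next
      proxy <- !is.null(guardians_of[[sid]])
      for (s in inst$scopes) {
        atoms <- if (identical(s$category, "economic")) {
          oracle_atoms("economic", part = if (length(s$economic_parts %||% character(0))) s$economic_parts)
        } else if (identical(s$category, "health")) {
          oracle_atoms("health",
                       part = if (length(s$health_parts %||% character(0))) s$health_parts,
                       temporal = if (length(s$health_temporal %||% character(0))) s$health_temporal)
        } else oracle_atoms(s$category)
        push(inst$date_of_completion,
             if (isTRUE(s$granted)) "grant" else "deny", atoms, proxy)
        if (isTRUE(s$future_contact)) {
          push(inst$date_of_completion, "grant", oracle_atoms("future_contact"), proxy)
        }
      }
    }
  }
  for (e in store$events) {
    if (!identical(paste0(e$actor$form_id, ":", e$actor$person_id), key)) next
    if (identical(e$event_type, "assent_given")) {
      push(e$date, "assent", "assent", FALSE)
      next
    }
    type <- if (e$event_type %in% c("consent_given", "reconsent")) "grant" else "deny"
    atoms <- if (identical(e$event_type, "future_contact_revoked")) {
      oracle_atoms("future_contact")
    } else if (is.null(e$target_scope)) {
      oracle_all_atoms()
    } else {
      oracle_atoms(e$target_scope$category, part = e$target_scope$part,
                   temporal = e$target_scope$temporal)
    }
    push(e$date, type, atoms, FALSE)
  }
  out
}

oracle_verdict <- function(store, key, category, subscope = NULL, query_date,
                           policy = assent_policy()) {
  if (length(store$instances) == 0) return("denied")
  qd <- as.Date(query_date)
  entries <- oracle_entries(store, key)
  entries <- entries[entries$date <= qd, , drop = FALSE]
  assent_seen <- any(entries$type == "assent")
  person <- NULL
  for (inst in store$instances) {
    if (startsWith(key, paste0(inst$form_id, ":"))) {
      for (p in inst$persons) {
        if (identical(paste0(inst$form_id, ":", p$id), key)) person <- p
      }
    }
  }
  atoms <- oracle_atoms(category, part = subscope$part %||% NULL,
                        temporal = subscope$temporal %||% NULL)
  states <- character(0)
  for (a in atoms) {
    ea <- entries[entries$atom == a, , drop = FALSE]
    if (nrow(ea) == 0) { states <- c(states, "none"); next }
    state <- "none"; state_proxy <- FALSE
    for (d in sort(unique(ea$date))) {
      day <- ea[ea$date == d, , drop = FALSE]
      if (any(day$type == "grant") && any(day$type == "deny")) {
        state <- "conflict"
      } else if (any(day$type == "grant")) {
        state <- "granted"; state_proxy <- all(day$proxy)
      } else {
        state <- "denied"
      }
    }
    if (identical(state, "granted") && state_proxy &&
        identical(policy$behaviour, "guardian_expires_at_age") &&
        !is.null(policy$assent_required_from_age) && !assent_seen) {
      dob <- person$date_of_birth
      expired <- is.null(dob) ||
        (length(seq(as.Date(dob), qd, by = "year")) - 1) >= policy$assent_required_from_age
      if (expired) state <- "proxy_expired"
    }
    states <- c(states, state)
  }
  if (all(states == "granted")) return("permitted")
  if (any(states %in% c("conflict", "proxy_expired"))) return("unknown")
  "denied"
}

# small random store: <= 5 persons, <= n_events events
random_small_store <- function(seed, n_events = 8) {
  set.seed(seed)
  n_inst <- sample(1:3, 1)
  profiles <- sample(c("generic", "elsa_like", "lsac_like"), n_inst, replace = TRUE)
  instances <- lapply(seq_len(n_inst), function(i) {
    inst <- generate_instance(study_profile(profiles[i]), seed = seed * 17 + i)
    inst$form_id <- sprintf("RS%d-%d", seed %% 1000, i)
    inst
  })
  store <- consent_store(instances, validate = FALSE)
  categories <- c("economic", "education", "legal", "family",
                  "mobile_phone_usage", "health", "future_contact")
  n_ev <- sample(0:n_events, 1)
  for (k in seq_len(n_ev)) {
    inst <- instances[[sample(n_inst, 1)]]
    pid <- sample(vapply(inst$persons, `[[`, character(1), "id"), 1)
    type <- sample(c("consent_given", "consent_withdrawn", "assent_given",
                     "dissent", "reconsent", "future_contact_revoked"), 1)
    target <- NULL
    if (type %in% c("consent_given", "consent_withdrawn", "reconsent", "dissent") &&
        runif(1) < 0.7) {
      cat <- sample(setdiff(categories, "future_contact"), 1)
      target <- list(category = cat)
      if (cat == "health" && runif(1) < 0.5) {
        target$part <- sample(ORACLE_PARTS$health, 1)
      }
      if (cat == "health" && runif(1) < 0.5) {
        target$temporal <- sample(ORACLE_TEMPORAL$health, 1)
      }
      if (cat == "economic" && runif(1) < 0.5) {
        target$part <- sample(ORACLE_PARTS$economic, 1)
      }
    }
    date <- format(as.Date("2016-01-01") + sample(0:1200, 1), "%Y-%m-%d")
    store <- apply_event(store, lifecycle_event(type, date, inst$form_id, pid, target))
  }
  store
}

store_person_keys <- function(store) {
  unlist(lapply(store$instances, function(inst) {
    paste0(inst$form_id, ":", vapply(inst$persons, `[[`, character(1), "id"))
  }), use.names = FALSE)
}

store_query_dates <- function(store) {
  dates <- as.Date(vapply(store$instances, `[[`, character(1),
                          "date_of_completion"))
  if (length(store$events) > 0) {
    dates <- c(dates, as.Date(vapply(store$events, `[[`, character(1), "date")))
  }
  format(sort(unique(c(min(dates) - 1, dates, dates + 1, max(dates) + 400))),
         "%Y-%m-%d")
}
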