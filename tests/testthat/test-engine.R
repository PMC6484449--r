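reg <- build_default_registry()

# one instance with a guardian consenting for an 8-year-old at completion
proxy_store <- function() {
  inst <- generate_instance(study_profile("lsac_like"), seed = 21)
  inst$form_id <- "PRX-1"
  inst$date_of_completion <- "2015-06-01"
  inst$persons[[1]]$signature$date <- "2015-06-01"
  inst$persons[[2]]$date_of_birth <- "2007-03-10"
  consent_store(list(inst), registry = reg)
}

test_that("an empty store denies by default, with a justification", {
  store <- consent_store(list(), registry = reg)
  d <- is_linkage_permitted(store, "F1:p1", "health", query_date = "2020-01-01")
  expect_identical(d$verdict, "denied")
  expect_identical(d$justification$rule, "default_deny")
  expect_identical(eligible_cohort(store, "health", "2020-01-01"), character(0))
})

test_that("an unknown person in a non-empty store is a lookup error", {
  store <- generate_population(2, seed = 1)
  expect_error(
    is_linkage_permitted(store, "NOPE:p1", "health", query_date = "2020-01-01"),
    "person not found")
})

test_that("withdrawal after a grant denies, citing the withdrawal event", {
  store <- generate_population(1, seed = 3)
  key <- paste0(store$instances[[1]]$form_id, ":p1")
  doc <- store$instances[[1]]$date_of_completion
  after <- format(as.Date(doc) + 100, "%Y-%m-%d")
  expect_identical(
    is_linkage_permitted(store, key, "health", query_date = after)$verdict,
    "permitted")
  store2 <- apply_event(store, lifecycle_event(
    "consent_withdrawn", after, store$instances[[1]]$form_id, "p1",
    target_scope = list(category = "health")))
  d <- is_linkage_permitted(store2, key, "health",
                            query_date = format(as.Date(after) + 1, "%Y-%m-%d"))
  expect_identical(d$verdict, "denied")
  expect_true(any(d$justification$rule == "withdrawal"))
  expect_true(any(grepl("consent_withdrawn", d$justification$ref)))
  # value semantics: the original store is untouched
  expect_length(store$events, 0)
  expect_identical(
    is_linkage_permitted(store, key, "health", query_date = after)$verdict,
    "permitted")
})

test_that("withdrawing a broader scope revokes the narrower scopes inside it", {
  store <- generate_population(1, seed = 5)
  form <- store$instances[[1]]$form_id
  doc <- as.Date(store$instances[[1]]$date_of_completion)
  store <- apply_event(store, lifecycle_event(
    "consent_withdrawn", format(doc + 10, "%Y-%m-%d"), form, "p1",
    target_scope = list(category = "health")))
  qd <- format(doc + 20, "%Y-%m-%d")
  d <- is_linkage_permitted(store, paste0(form, ":p1"), "health",
                            subscope = list(part = "tests_and_assessments"),
                            query_date = qd)
  expect_identical(d$verdict, "denied")
})

test_that("scope selectors are matched exactly over enumerated sub-parts", {
  inst <- generate_instance(study_profile("generic"), seed = 7)
  inst$form_id <- "SCP-1"
  inst$scopes <- list(record_scope("health", granted = TRUE,
                                   health_parts = "tests_and_assessments"))
  store <- consent_store(list(inst), registry = reg)
  qd <- format(as.Date(inst$date_of_completion) + 1, "%Y-%m-%d")
  expect_identical(
    is_linkage_permitted(store, "SCP-1:p1", "health",
                         subscope = list(part = "tests_and_assessments"),
                         query_date = qd)$verdict,
    "permitted")
  expect_identical(
    is_linkage_permitted(store, "SCP-1:p1", "health",
                         subscope = list(part = "treatments_and_management"),
                         query_date = qd)$verdict,
    "denied")
  # the whole category is broader than the grant
  expect_identical(
    is_linkage_permitted(store, "SCP-1:p1", "health", query_date = qd)$verdict,
    "denied")
})

test_that("temporal sub-scopes match against the grant's qualifiers", {
  inst <- generate_instance(study_profile("elsa_like"), seed = 8) # past only
  inst$form_id <- "TMP-1"
  store <- consent_store(list(inst), registry = reg)
  qd <- format(as.Date(inst$date_of_completion) + 1, "%Y-%m-%d")
  expect_identical(
    is_linkage_permitted(store, "TMP-1:p1", "health",
                         subscope = list(temporal = "past"),
                         query_date = qd)$verdict, "permitted")
  expect_identical(
    is_linkage_permitted(store, "TMP-1:p1", "health",
                         subscope = list(temporal = "future"),
                         query_date = qd)$verdict, "denied")
})

test_that("assent policy truth table over behaviour x assent event", {
  qd <- "2023-06-02" # subject aged 16; assent threshold 12
  key <- "PRX-1:p2"
  persists <- assent_policy(12, "guardian_persists_until_assent_event")
  expires <- assent_policy(12, "guardian_expires_at_age")

  # guardian persists, no assent event: proxy grant stands
  s1 <- proxy_store()
  expect_identical(
    is_linkage_permitted(s1, key, "health", query_date = qd,
                         policy = persists)$verdict, "permitted")

  # guardian persists, assent recorded: still permitted
  s2 <- apply_event(s1, lifecycle_event("assent_given", "2020-01-01", "PRX-1", "p2"))
  expect_identical(
    is_linkage_permitted(s2, key, "health", query_date = qd,
                         policy = persists)$verdict, "permitted")

  # guardian expires at age, no assent: a genuine gap
  d3 <- is_linkage_permitted(s1, key, "health", query_date = qd,
                             policy = expires)
  expect_identical(d3$verdict, "unknown")
  expect_true(any(d3$justification$rule == "proxy_expired_without_assent"))

  # guardian expires at age, but assent was recorded: permitted again
  expect_identical(
    is_linkage_permitted(s2, key, "health", query_date = qd,
                         policy = expires)$verdict, "permitted")

  # before the subject reaches the age, the proxy grant is valid either way
  expect_identical(
    is_linkage_permitted(s1, key, "health", query_date = "2016-01-01",
                         policy = expires)$verdict, "permitted")

  # dissent by the subject denies regardless of policy
  s4 <- apply_event(s1, lifecycle_event("dissent", "2021-01-01", "PRX-1", "p2"))
  expect_identical(
    is_linkage_permitted(s4, key, "health", query_date = qd,
                         policy = persists)$verdict, "denied")
})

test_that("contradictory same-day events yield unknown", {
  store <- generate_population(1, seed = 9)
  form <- store$instances[[1]]$form_id
  doc <- as.Date(store$instances[[1]]$date_of_completion)
  day <- format(doc + 30, "%Y-%m-%d")
  store <- apply_event(store, lifecycle_event(
    "consent_withdrawn", day, form, "p1", list(category = "health")))
  store <- apply_event(store, lifecycle_event(
    "reconsent", day, form, "p1", list(category = "health")))
  d <- is_linkage_permitted(store, paste0(form, ":p1"), "health",
                            query_date = format(doc + 40, "%Y-%m-%d"))
  expect_identical(d$verdict, "unknown")
  expect_true(any(d$justification$rule == "same_day_conflict"))
})

test_that("future contact is queryable as its own pseudo-category", {
  store <- generate_population(1, seed = 10)
  form <- store$instances[[1]]$form_id
  doc <- as.Date(store$instances[[1]]$date_of_completion)
  qd <- format(doc + 5, "%Y-%m-%d")
  expect_identical(
    is_linkage_permitted(store, paste0(form, ":p1"), "future_contact",
                         query_date = qd)$verdict, "permitted")
  store <- apply_event(store, lifecycle_event(
    "future_contact_revoked", qd, form, "p1"))
  expect_identical(
    is_linkage_permitted(store, paste0(form, ":p1"), "future_contact",
                         query_date = format(doc + 6, "%Y-%m-%d"))$verdict,
    "denied")
})

test_that("apply_event rejects dangling references", {
  store <- generate_population(1, seed = 11)
  expect_error(apply_event(store, lifecycle_event(
    "consent_withdrawn", "2020-01-01", "NOPE", "p1")), "unknown instance")
  expect_error(apply_event(store, lifecycle_event(
    "consent_withdrawn", "2020-01-01", store$instances[[1]]$form_id, "p9")),
    "unknown person")
})

test_that("eligible cohort equals the per-person replay", {
  store <- generate_population(30, withdrawal_rate = 0.3, proxy_rate = 0,
                               seed = 13)
  w <- length(store$events)
  qd <- "2030-01-01"
  cohort <- eligible_cohort(store, "health", qd)
  expect_identical(length(cohort), 30L - w)
  expect_identical(cohort, sort(cohort, method = "radix"))
  for (key in store_person_keys(store)) {
    verdict <- is_linkage_permitted(store, key, "health", query_date = qd)$verdict
    expect_identical(key %in% cohort, identical(verdict, "permitted"), label = key)
  }
})

test_that("verdicts before any event match the empty-store verdict", {
  store <- generate_population(3, withdrawal_rate = 1, proxy_rate = 0, seed = 14)
  early <- "1990-01-01"
  for (key in store_person_keys(store)) {
    expect_identical(
      is_linkage_permitted(store, key, "health", query_date = early)$verdict,
      "denied")
  }
})

test_that("decisions are deterministic", {
  store <- random_small_store(99)
  key <- store_person_keys(store)[1]
  d1 <- is_linkage_permitted(store, key, "health", query_date = "2018-06-01")
  d2 <- is_linkage_permitted(store, key, "health", query_date = "2018-06-01")
  expect_identical(d1, d2)
})

test_that("appending a withdrawal never flips a verdict to permitted", {
  categories <- c("health", "economic", "future_contact")
  for (seed in 1:12) {
    store <- random_small_store(seed)
    keys <- store_person_keys(store)
    inst <- store$instances[[1 + seed %% length(store$instances)]]
    wd <- lifecycle_event(
      "consent_withdrawn",
      format(as.Date("2016-01-01") + (seed * 37) %% 1200, "%Y-%m-%d"),
      inst$form_id, inst$persons[[1]]$id,
      target_scope = if (seed %% 2) list(category = "health"))
    store2 <- apply_event(store, wd)
    all_dates <- store_query_dates(store2)
    dates <- all_dates[unique(c(1, ceiling(length(all_dates) / 2),
                                length(all_dates)))]
    for (key in keys) for (cat in categories) {
      for (qd in dates) {
        v1 <- is_linkage_permitted(store, key, cat, query_date = qd)$verdict
        v2 <- is_linkage_permitted(store2, key, cat, query_date = qd)$verdict
        if (identical(v1, "denied")) {
          expect_false(identical(v2, "permitted"),
                       label = sprintf("seed %d %s %s %s", seed, key, cat, qd))
        }
      }
    }
  }
})
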