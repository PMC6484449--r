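reg <- build_default_registry()

test_that("profiles emulate the documented form structures", {
  clsa <- generate_instance(study_profile("clsa_like"), seed = 1)
  statements <- Filter(function(q) identical(q$kind, "statement"), clsa$questions)
  expect_length(statements, 3)

  elsa <- generate_instance(study_profile("elsa_like"), seed = 1)
  expect_false(is.null(elsa$instructions_for_next_steps))
  expect_true(any(vapply(elsa$persons, function(p)
    identical(p$kind, "professional"), logical(1))))

  lsac <- generate_instance(study_profile("lsac_like"), seed = 1)
  proxies <- Filter(function(p) !is.null(p$consents_on_behalf_of), lsac$persons)
  expect_length(proxies, 1)
  expect_identical(proxies[[1]]$kind, "non_professional")
  expect_true(any(vapply(lsac$persons, function(p)
    identical(p$role, "consent_subject"), logical(1))))
  expect_length(lsac$informational_documents, 1)
  expect_false(is.null(lsac$general$aim))
})

test_that("generation is deterministic and leaves the caller's RNG alone", {
  a <- generate_instance(study_profile("elsa_like"), seed = 7)
  b <- generate_instance(study_profile("elsa_like"), seed = 7)
  expect_identical(a, b)
  expect_identical(write_instance(a, "json"), write_instance(b, "json"))
  expect_false(instances_equal(a, generate_instance(study_profile("elsa_like"),
                                                    seed = 8)))
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(generate_instance(study_profile("generic"), 1))
  expect_identical(runif(3), before)
})

test_that("every generated instance validates with zero errors", {
  for (pn in c("generic", "elsa_like", "clsa_like", "lsac_like")) {
    for (s in c(1, 99, 4242)) {
      inst <- generate_instance(study_profile(pn), seed = s)
      expect_identical(nrow(validate_instance(inst, reg)), 0L,
                       label = sprintf("%s seed %d", pn, s))
    }
  }
})

test_that("names come from the packaged fictitious wordlist", {
  wl <- readLines(system.file("extdata", "wordlist.txt",
                              package = "consentlink"))
  wl <- wl[!grepl("^#", wl) & nzchar(wl)]
  words <- vapply(strsplit(wl, " "), `[[`, character(1), 2)
  inst <- generate_instance(study_profile("lsac_like"), seed = 31)
  for (p in inst$persons) {
    parts <- strsplit(p$full_name, " ")[[1]]
    expect_true(all(parts %in% words), label = p$full_name)
  }
})

test_that("profile invariants are enforced", {
  expect_error(study_profile("generic", n_statements = 0), "at least 1")
  expect_error(study_profile("lsac_like", child_subject_with_proxy = FALSE),
               "implies a child subject")
})

test_that("population generation respects sizes, rates, and seeds", {
  expect_length(generate_population(0, seed = 1)$instances, 0)
  none <- generate_population(50, withdrawal_rate = 0, proxy_rate = 0, seed = 2)
  expect_length(none$events, 0)

  pop <- generate_population(200, withdrawal_rate = 0.25, proxy_rate = 0.1,
                             seed = 3)
  expect_length(pop$instances, 200)
  w <- length(pop$events)
  # exact binomial 99% interval for Binomial(200, 0.25)
  expect_gte(w, qbinom(0.005, 200, 0.25))
  expect_lte(w, qbinom(0.995, 200, 0.25))
  # proxied instances carry a consent subject with a guardian link
  n_proxy <- sum(vapply(pop$instances, function(inst) {
    any(vapply(inst$persons, function(p)
      !is.null(p$consents_on_behalf_of), logical(1)))
  }, logical(1)))
  expect_gte(n_proxy, qbinom(0.005, 200, 0.1))
  expect_lte(n_proxy, qbinom(0.995, 200, 0.1))

  expect_identical(
    consentlink:::store_entries(generate_population(20, 0.3, 0.2, seed = 5)),
    consentlink:::store_entries(generate_population(20, 0.3, 0.2, seed = 5)))
  expect_error(generate_population(10, withdrawal_rate = 1.5, seed = 1),
               "withdrawal_rate")
  expect_error(generate_population(10, proxy_rate = -0.1, seed = 1),
               "proxy_rate")
})
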