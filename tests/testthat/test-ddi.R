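reg <- build_default_registry()
tab <- load_mapping_table(registry = reg)

test_that("mapping table and registry are in bijection", {
  expect_setequal(tab$model_element, names(reg$elements))
  expect_identical(anyDuplicated(tab$model_element), 0L)
  # tampering is caught at load: a dropped row and an orphan row both fail
  path <- withr::local_tempfile(fileext = ".json")
  raw <- jsonlite::fromJSON(system.file("extdata", "ddi_mapping.json",
                                        package = "consentlink"),
                            simplifyVector = FALSE)
  jsonlite::write_json(raw[-1], path, auto_unbox = TRUE)
  expect_error(load_mapping_table(path, registry = reg), "absent from table")
  extra <- c(raw, list(list(model_element = "not_in_registry",
                            ddi_elements = list(), category = "unmapped",
                            note = "orphan")))
  jsonlite::write_json(extra, path, auto_unbox = TRUE)
  expect_error(load_mapping_table(path, registry = reg), "not in registry")
})

test_that("every mapping row honours its category contract", {
  for (i in seq_len(nrow(tab))) {
    els <- tab$ddi_elements[[i]]
    switch(tab$category[i],
      direct = {
        expect_gt(length(els), 0)
        expect_false("Note" %in% els)
      },
      workaround = expect_true("Note" %in% els),
      unmapped = expect_length(els, 0)
    )
  }
})

test_that("the mappings the appraisal names verbatim are present", {
  row <- function(id) tab[tab$model_element == id, ]
  expect_identical(row("full_name")$category, "direct")
  expect_identical(row("full_name")$ddi_elements[[1]], "FullName")
  expect_identical(row("location")$ddi_elements[[1]], "LocationName")
  expect_identical(row("nationality")$ddi_elements[[1]], "Country")
  expect_identical(row("telephone")$ddi_elements[[1]], "TelephoneNumber")
  expect_identical(row("email")$ddi_elements[[1]], "Email")
  expect_identical(row("date")$ddi_elements[[1]], "Date")
  expect_true(all(c("ResponseText", "CodeList", "CodeListName",
                    "CodeListReference") %in% row("responses")$ddi_elements[[1]]))
  expect_identical(row("personal_records")$ddi_elements[[1]], "CodeListGroup")
  expect_identical(row("funding_bodies")$ddi_elements[[1]], "FundingInformation")
  expect_setequal(row("withdrawal_procedure")$ddi_elements[[1]],
                  c("LifecycleEvent", "EventType"))
  for (id in c("consents_on_behalf_of", "confirmation_of_understanding",
               "undertakings", "confirmatory_information",
               "treatments_and_management", "tests_and_assessments")) {
    expect_identical(row(id)$category, "workaround", label = id)
    expect_true("Note" %in% row(id)$ddi_elements[[1]], label = id)
  }
  expect_identical(row("biological_samples")$category, "unmapped")
  expect_identical(row("sample_acquisition")$category, "unmapped")
})

test_that("coverage report is order-invariant and robust to empty input", {
  rep <- coverage_report(reg, tab)
  shuffled <- reg
  set.seed(1)
  shuffled$elements <- shuffled$elements[sample(names(shuffled$elements))]
  expect_identical(coverage_report(shuffled, tab), rep)
  # degenerate: no elements at all, still no division error
  empty_reg <- structure(list(version = "0", components = reg$components,
                              elements = list()),
                         class = "consent_registry")
  empty_tab <- tab[0, ]
  rep0 <- coverage_report(empty_reg, empty_tab)
  expect_true(all(rep0$n == 0))
  expect_true(all(rep0$direct_pct == 0))
  # shares within each component add to 100 (within rounding)
  pos <- rep[rep$n > 0, ]
  expect_true(all(abs(pos$direct_pct + pos$workaround_pct + pos$unmapped_pct
                      - 100) <= 0.2))
  expect_identical(rowSums(rep[, c("direct", "workaround", "unmapped")]),
                   as.numeric(rep$n), ignore_attr = TRUE)
})

studyunit_nodes <- function(xml, name) {
  doc <- xml2::read_xml(rawToChar(xml))
  xml2::xml_find_all(doc, sprintf("//*[local-name()='%s']", name))
}

test_that("StudyUnit export carries lifecycle events and code lists", {
  inst <- read_instance(system.file("extdata", "fixtures", "clsa_like.json",
                                    package = "consentlink"), "json")
  ev <- lifecycle_event("consent_withdrawn", "2020-05-01", inst$form_id, "p1",
                        target_scope = list(category = "health"))
  xml <- export_study_unit(inst, tab, events = list(ev), registry = reg)
  le <- studyunit_nodes(xml, "LifecycleEvent")
  expect_length(le, 1)
  expect_length(xml2::xml_find_all(le[[1]], "*[local-name()='EventType']"), 1)
  expect_gt(length(studyunit_nodes(xml, "CodeList")), 0)
  expect_gt(length(studyunit_nodes(xml, "CodeListReference")), 0)
  # no events, no LifecycleEvent elements
  xml0 <- export_study_unit(inst, tab, registry = reg)
  expect_length(studyunit_nodes(xml0, "LifecycleEvent"), 0)
  # several events are supported
  ev2 <- lifecycle_event("reconsent", "2021-05-01", inst$form_id, "p1")
  xml2 <- export_study_unit(inst, tab, events = list(ev, ev2), registry = reg)
  expect_length(studyunit_nodes(xml2, "LifecycleEvent"), 2)
})

test_that("workaround Notes are machine-recoverable and extensions separated", {
  inst <- generate_instance(study_profile("lsac_like"), seed = 5)
  inst$scopes[[1]]$biological_samples <-
    list(type_of_test = "blood test", storage_of_sample = "frozen",
         lab_name = "Synthetic Lab", lab_site = "Mocktown")
  inst$extensions <- list(jurisdiction = "Exampleland")
  xml <- export_study_unit(inst, tab, registry = reg)
  notes <- studyunit_nodes(xml, "Note")
  expect_true(any(grepl("model_element=consents_on_behalf_of",
                        xml2::xml_text(notes))))
  expect_true(all(grepl("^model_element=.+; value=", xml2::xml_text(notes))))
  ext <- studyunit_nodes(xml, "ExtensionBlock")
  expect_length(ext, 1)
  payload <- jsonlite::fromJSON(xml2::xml_text(ext[[1]]), simplifyVector = FALSE)
  expect_identical(payload$biological_samples[[1]]$type_of_test, "blood test")
  expect_identical(payload$extensions$jurisdiction, "Exampleland")
  # unmapped content appears nowhere outside the extension block
  doc <- xml2::read_xml(rawToChar(xml))
  hits <- xml2::xml_find_all(doc, "//*[contains(text(), 'blood test')]")
  expect_true(all(xml2::xml_name(hits) == "ExtensionBlock"))
})

test_that("export totality: every populated field surfaces in the output", {
  for (pn in c("elsa_like", "clsa_like", "lsac_like")) {
    inst <- read_instance(system.file("extdata", "fixtures",
                                      paste0(pn, ".json"),
                                      package = "consentlink"), "json")
    cen <- export_census(inst, export_study_unit(inst, tab, registry = reg))
    expect_true(all(cen$found),
                label = paste(pn, paste(cen$value[!cen$found], collapse = ", ")))
  }
})

test_that("export refuses an invalid instance", {
  inst <- generate_instance(study_profile("generic"), seed = 1)
  inst$persons[[1]]$consents_on_behalf_of <- list(person = "p1",
                                                  relationship = "self")
  expect_error(export_study_unit(inst, tab, registry = reg),
               class = "consentlink_validation_error")
})
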