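Package: consentlink
Title: Consent Metadata Management for Record Linkage in Longitudinal Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A metadata registry and toolset for recording informed consent for
    record linkage in longitudinal health research studies. Provides a packaged
    element/attribute registry built with object-oriented inheritance and
    aggregation (People, Consent form, Personal records, Informational
    material), reads and writes consent-form instance documents in JSON and XML
    dialects with registry-driven validation, exports instances as DDI
    3.2-style StudyUnit XML with a per-component mapping coverage report, and
    answers linkage-permission queries over stores of consent instances and
    lifecycle events, honouring scope, temporality, withdrawal, and proxy
    consent with assent policies. Includes a seeded synthetic fixture generator
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
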