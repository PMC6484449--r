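# consentlink

Consent metadata management for record linkage in longitudinal health studies.

## The problem

Longitudinal cohort studies routinely ask participants for consent to link
their study data to external records — health, economic, education, legal,
family, and mobile-phone-usage records. No common standard exists for
recording *what* was consented to, *by whom* (possibly a guardian on behalf
of a child), *when*, and *whether it still stands* after withdrawals or
re-consent. The result is ad-hoc paperwork that delays or blocks linkage
approvals.

consentlink implements a structured consent metadata model for this setting,
aimed at study data managers, governance stakeholders, and metadata
engineers. It provides:

* **A packaged element registry** — the model's element/attribute taxonomy
  across four components (*People*, *Consent form*, *Personal records*,
  *Informational material*), related by object-oriented **inheritance**
  (children acquire ancestor attributes: an academic institution inherits
  `organization_name` and `ethics_approval_reference` from the organization
  element) and **aggregation** (composites built from parts: questions are
  composed of logic, responses, and purpose inside the data collection).
* **Instance documents** — completed consent forms in a canonical JSON
  dialect (XML equivalent included), with registry-driven validation.
* **DDI 3.2 export and appraisal** — every model element carries a mapping
  verdict (`direct`, `workaround` via the `Note` element, or `unmapped`);
  instances export as DDI-style `StudyUnit` XML; `coverage_report()`
  tallies the per-component verdicts.
* **A consent-resolution engine** — answers "may I link record category X
  for person P on date D?" by chronologically replaying granted scopes and
  lifecycle events (withdrawal, assent, dissent, re-consent), with
  default-deny semantics, scope/temporal selectors, and pluggable assent
  policies for maturing child subjects.
* **A seeded fixture generator** — synthetic consent forms and populations
  emulating the structural patterns of real cohort-study forms, using an
  obviously fictitious name list.

## The resolution model in brief

Every consent scope expands to a set of atoms
*(category, sub-part, temporal)* — e.g. a health grant restricted to
`tests_and_assessments` in the `past`. A query is **permitted** iff every
atom under its selector is in the granted state after replaying all entries
dated on or before the query date, last-event-wins per atom; withdrawal of
a broader scope revokes every narrower scope within it. Contradictory
same-day events (forms carry dates, not times) and lapsed proxy consent
under a `guardian_expires_at_age` policy yield **unknown**; everything else
defaults to **denied**.

## Worked example

```r
library(consentlink)

reg <- build_default_registry()
record_categories(reg)
#> [1] "economic"           "education"          "legal"
#> [4] "family"             "mobile_phone_usage" "health"

coverage_report(reg, load_mapping_table())
#> DDI 3.2 mapping coverage by model component
#>               component  n direct workaround unmapped direct_pct mapped_pct
#>                  people 12      6          6        0      50.0%     100.0%
#>            consent_form 15     12          3        0      80.0%     100.0%
#>        personal_records 17     13          4        0      76.5%     100.0%
#>  informational_material 12      6          4        2      50.0%      83.3%
#>                 overall 56     37         17        2      66.1%      96.4%
```

Half of the People elements map directly to DDI 3.2 (`FullName`,
`TelephoneNumber`, `Email`, `LocationName`, `Country`, `Date`); every
personal-records element is mapped at least via the `Note` workaround; the
consent-form component maps best (a consent form is a survey instrument,
which is exactly what DDI captures); biological-samples metadata has no DDI
home at all.

```r
store <- generate_population(3, withdrawal_rate = 0, proxy_rate = 0, seed = 1)
is_linkage_permitted(store, "POP-00001:p1", "health", query_date = "2020-01-01")
#> verdict: permitted
#>   - [grant] POP-00001/scopes/1

store <- apply_event(store, lifecycle_event(
  "consent_withdrawn", "2021-03-01", "POP-00001", "p1",
  target_scope = list(category = "health")))
is_linkage_permitted(store, "POP-00001:p1", "health", query_date = "2021-06-01")
#> verdict: denied
#>   - [withdrawal] event/1:consent_withdrawn@2021-03-01
```

The verdict lines are the engine's justification trail: each row names the
scope or lifecycle event that determined the decision.

A command-line interface wraps the same functions
(`validate`, `export-ddi`, `coverage-report`, `query`,
`generate-fixtures`); see `inst/cli/consentlink` and `?consent_cli`.

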