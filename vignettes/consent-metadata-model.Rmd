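---
title: "The consent metadata model: design, semantics, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The consent metadata model: design, semantics, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consentlink)
```

## The model

consentlink implements a metadata model for recording informed consent for
record linkage in longitudinal health studies. The model organizes its
elements into four components — *People*, *Consent form*, *Personal
records*, and *Informational material* — and uses two object-oriented
relations to keep the element count small:

* **inheritance**: a child element acquires every ancestor's attributes.
  `academic_institution` inherits `organization_name` and
  `ethics_approval_reference` from `organization`; `professional` and
  `non_professional` specialize `person`, so the shared demographic parts
  are declared once.
* **aggregation**: composite elements are declared from parts with
  cardinalities. `questions` is composed of `logic`, `responses`, and
  `purpose`, and is itself a part of `data_collection` alongside
  `method_of_collection` (self-completion, interviewer-administered,
  online, telephone — supporting mixed-mode consent). Parts default to
  unbounded repetition; minima are imposed only where an instance
  invariant requires presence (e.g. a form must carry a
  `date_of_completion` and at least one non-professional person).

The registry ships as a versioned JSON file
(`inst/extdata/registry.json`) so non-code consumers can audit the model.
It records the model in its *final* state: the date of completion sits on
the consent form rather than on people; the economic record category is
composed of separate benefits-claims, NI-contributions, and tax elements;
health records carry past/present/future temporal children plus
treatments-and-management (with use-of-health-services) and
tests-and-assessments (with rights-to-results); and biological samples form
their own element with `type_of_test`, `storage_of_sample`, `lab_name`, and
`lab_site` attributes, which widens the scope for dynamic, per-test
consent. Earlier intermediate states of the model are deliberately not
representable.

Design choices that were genuinely open:

* Canonical ids are `lower_snake_case` tokens derived from display labels;
  display labels preserve the field's wording, giving stable machine keys
  with faithful human names.
* `future_contact` (consent to be contacted again) is modelled as a flag on
  a record scope and as a queryable pseudo-category in the engine, not as a
  seventh record category: it cross-cuts the record taxonomy rather than
  naming a class of linkable records.
* The categories without published sub-structure (education, legal, family,
  mobile phone usage) are leaf elements with a free-text `detail`
  attribute.
* `confirmatory_information` is free text; no enumeration of its content
  exists to model.
* A person may carry an optional `date_of_birth`. It is not part of the
  form's printed demographic minimum, but without it no age-based assent
  policy is computable; when it is absent under an age-expiry policy the
  engine answers `unknown` rather than guessing.
* Biological-samples metadata is aggregated under `health` but counted with
  the informational-material component in the DDI appraisal, which is where
  that verdict belongs; keeping it inside personal records would contradict
  the appraisal's "all personal-records elements mapped" outcome.

## Instance documents and validation

JSON is the primary dialect: human-diffable and schema-checkable. An XML
dialect is provided because the DDI ecosystem is XML-native; both map onto
the same canonical tree, so `read(write(x))` is a structural identity in
either format and serialization is byte-deterministic. Encoding is fixed to
UTF-8; dates are ISO 8601 calendar dates throughout (forms are dated, never
timestamped).

Unknown keys are *errors*, not warnings: the model's value is
standardization, and silent extension defeats it. Forward compatibility
goes through an explicit `extensions` container, the only place
unregistered keys may live. The remaining validation rules codify the
model's structural invariants — proxy links must resolve and may not be
reflexive, person kinds must match roles, question logic may only reference
earlier questions, responses must answer existing questions, scope
sub-parts must match their category, and no signature may postdate the
form's completion. Issues are returned as an ordered table (`severity`,
`code`, `path`, `message`), never thrown away.

## DDI 3.2 mapping and export

Every registry element has exactly one fate under DDI 3.2, recorded in a
packaged, auditable table (`inst/extdata/ddi_mapping.json`):

* `direct` — DDI elements carry it natively (`FullName`,
  `TelephoneNumber`, `Email`, `LocationName`, `Country`, `Date`,
  `ModeOfCollection`, `CodeList`/`CodeListGroup` machinery,
  `FundingInformation`, `EventType` + `LifecycleEvent`, ...).
* `workaround` — a `Note` attached to a maintainable object carries it,
  with the payload convention `model_element=<id>; value=<json>` so the
  workaround stays machine-recoverable. Proxy consent, confirmation of
  understanding, signatures, undertakings, confirmatory information, and
  the treatments/tests health sub-elements live here.
* `unmapped` — DDI offers nothing; applies to biological-samples use and
  acquisition. Exported instances carry such content only in a clearly
  separated extension block under the project's own namespace.

"Mapped" in the coverage report means direct ∪ workaround: that is the only
reading under which every personal-records element counts as mapped while
two of them lack a direct link. The per-component censuses behind the
printed shares are 12 People elements (6 direct), 15 consent-form elements
(12 direct), 17 personal-records elements (13 direct, 4 workaround), and 12
informational-material elements (6 direct, 4 workaround, 2 unmapped).
Where the appraisal names a DDI element explicitly the table uses it
verbatim; the remaining rows use the nearest element of DDI 3.2's published
vocabulary. The `StudyUnit` export emits well-formed, namespace-tagged XML
with DDI element names; it is *not* validated against the official DDI XSD
(that would make the toolchain depend on downloading the standard's schema
files), so well-formedness plus the package's own structural checks — and
an export-totality census asserting that every populated field surfaces
somewhere in the output — are the contract.

## Resolution semantics

The engine answers linkage queries over an atom lattice. Every selector
expands to atoms *(category, sub-part, temporal)*: health crosses its four
sub-parts with past/present/future (the temporal qualifiers are interpreted
relative to the form's completion date — "past" covers records predating
it); economic crosses its three composed elements; the leaf categories and
the `future_contact` pseudo-category are single atoms. A grant with an
empty sub-part or temporal set is unrestricted within its category.

Replay rules, in order:

1. **Default-deny.** No matching grant means `denied`, never `unknown`;
   `unknown` is reserved for genuine conflicts and policy-expiry gaps.
2. Each granted scope acts as a consent entry dated at the form's
   completion; each lifecycle event contributes dated entries for the atoms
   under its target selector (no selector = the whole form). Withdrawal of
   a broader scope therefore revokes every narrower scope inside it — the
   simplest total rule, since the model describes withdrawal but not
   granularity conflicts.
3. **Last-event-wins per atom.** Only the latest entry group on or before
   the query date matters. A grant and a denial on the same calendar day
   are unordered (forms carry no time of day) and give `unknown`.
4. A query is `permitted` iff *every* atom under its selector is granted;
   any conflicted or expired atom makes it `unknown`; otherwise `denied`.
   Querying a whole category against a grant of one sub-part is therefore
   denied — selectors match exactly over the enumerated sub-parts.

Proxy consent (a guardian's `consents_on_behalf_of` link) attaches the
form's grants to the consent subject. Because the balance between a
guardian's consent and a maturing subject's assent is study- and
jurisdiction-specific, the mechanics are a pluggable `assent_policy()`:
under `guardian_persists_until_assent_event` the proxy grant stands until
the subject's own assent/dissent events; under `guardian_expires_at_age` it
lapses at the configured age unless an assent event is on record, and the
engine reports `unknown` for the gap. No default age is asserted. The
precedence between a guardian's withdrawal and a matured subject's earlier
assent is likewise left to the event record: events are replayed by date
regardless of which party recorded them.

Every decision carries a justification trail naming the scopes and events
that determined it, so governance reviews can audit the verdict.

## The synthetic-data generator

The generator emulates the three-part flow common to cohort-study consent
forms — demographics, then consent questions/statements, then confirmation
by signing and dating — under three named profiles: `elsa_like`
(interviewer-administered, two statements, instructions for what to do with
the two copies of the form, a past-restricted health scope plus a
fully-composed economic scope), `clsa_like` (three consent statements),
and `lsac_like` (a child consent subject aged roughly 6–10 at completion
with a guardian proxy, introductory aim/undertakings, and an information
sheet). Completion dates are drawn from 2015–2016, matching a study wave;
one question per multi-statement form carries branching logic to exercise
the logic-order rule. Populations attach whole-form withdrawal events to a
binomial fraction of instances 1–365 days after completion.

Generation is deterministic per `(profile, seed)`: each call seeds its own
generator and restores the caller's RNG state, and identical calls
serialize byte-identically. Names, places, and nationalities come from a
packaged, obviously fictitious wordlist — a consent tool should not emit
realistic personal data even in fixtures.

What the fixtures do **not** emulate: real form wording and layout, scanned
or PDF artefacts, inconsistent historical paperwork, free-text answers, or
jurisdiction-specific rules. Passing tests on these fixtures demonstrates
the machinery's correctness on structurally faithful input, not robustness
to the noise of real archives.

## Numerical and procedural choices

* Coverage percentages are rounded to one decimal; an empty registry
  reports zeros rather than dividing by zero.
* Ages are completed civil years (anniversary convention; a 29 February
  birthday matures on 1 March in common years).
* Validation output is sorted by path, making it deterministic and
  diff-friendly; ties break on the issue code.
* Issue severities are binary (`error`/`warning`); every invariant listed
  above is an error, and serialization/export refuse instances with any
  error-severity issue.
* The test suite sizes its property runs to be thorough yet quick: 500
  generated instances for round-trip identity, 1,000 seeded stores
  (≤ 5 persons, ≤ 8 events each) for engine-versus-oracle equivalence with
  queries at every date in each store's event span, and 40 stores for
  withdrawal monotonicity. The acceptance script uses 200 instances and
  300 stores for the same properties.

## Known limitations

* The DDI export is one-way; arbitrary DDI documents are not imported.
* The official DDI 3.2 XSD is not consulted; conformance is structural.
* The engine governs consent metadata only — it does not perform record
  linkage, and it encodes no jurisdiction-specific legal rules, which
  change too quickly to hard-code.
* Consent captured only in prose (the interviewee's reasoning, wording
  effectiveness) is out of scope; the model records structure, not
  rhetoric.
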