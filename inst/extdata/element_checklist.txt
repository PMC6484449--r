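# Display labels that must each resolve to exactly one registry element.
Person
Non-professional
Professional
Full name
Date
Signature
Confirmation of understanding
Consents on behalf of
Consent form
Organization
Academic institution
General
Aim
Undertakings
Confirmatory information
Data collection
Questions
Logic
Responses
Purpose
Method of collection
Instructions for next steps
Date of completion
Personal records
Economic
Benefits claims
NI contributions
Tax
Education
Legal
Family
Mobile phone usage
Health
Past
Present
Future
Treatments and management of conditions
Use of health services
Tests and assessments
Rights to results
Informational document
Study
Aims
Contact details
Funding bodies
Objectives
Reviewers
Research
Biological samples
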