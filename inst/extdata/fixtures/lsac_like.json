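{
  "form_id": "LSAC-18753",
  "study_name": "Exampleton Synthetic Cohort",
  "organizations": [
    {
      "organization_name": "University of Mocktown",
      "ethics_approval_reference": "REC-9091",
      "subtype": "academic_institution"
    }
  ],
  "persons": [
    {
      "id": "p1",
      "full_name": "Dana Fakeson",
      "role": "interviewee",
      "kind": "non_professional",
      "contact": {
        "telephone": "+00 7972913",
        "email": "guardian128@example.invalid",
        "location": "Stubbington",
        "nationality": "Exampleland"
      },
      "signature": {
        "signed": true,
        "date": "2016-07-14"
      },
      "confirmation_of_understanding": true,
      "consents_on_behalf_of": {
        "person": "p2",
        "relationship": "parent"
      }
    },
    {
      "id": "p2",
      "full_name": "Elia Mockwell",
      "role": "consent_subject",
      "kind": "non_professional",
      "date_of_birth": "2007-12-20",
      "signature": {
        "signed": false
      },
      "confirmation_of_understanding": false
    }
  ],
  "questions": [
    {
      "id": "q1",
      "text": "I agree that my study records may be linked to my health records.",
      "kind": "statement",
      "responses": {
        "type": "coded",
        "code_list": "consent_yes_no",
        "values": [
          "yes",
          "no"
        ]
      },
      "purpose": "establish consent for record linkage",
      "method_of_collection": "self_completion"
    },
    {
      "id": "q2",
      "text": "I agree that my study records may be linked to my economic records.",
      "kind": "statement",
      "logic": {
        "question": "q1",
        "response": "yes"
      },
      "responses": {
        "type": "coded",
        "code_list": "consent_yes_no",
        "values": [
          "yes",
          "no"
        ]
      },
      "purpose": "establish consent for record linkage",
      "method_of_collection": "self_completion"
    }
  ],
  "responses": {
    "q1": "yes",
    "q2": "yes"
  },
  "scopes": [
    {
      "category": "health",
      "granted": true,
      "future_contact": true
    }
  ],
  "date_of_completion": "2016-07-14",
  "general": {
    "aim": "This study follows children and their families over time.",
    "undertakings": "The study will keep your information secure.",
    "confirmatory_information": "You may keep a copy of this form."
  },
  "informational_documents": [
    {
      "accessibility": "online and on paper",
      "audience": "participants and guardians",
      "type": "information_sheet",
      "study": {
        "aims": "Describe the life course of a synthetic cohort.",
        "contact_details": "office26@example.invalid",
        "funding_bodies": [
          "Synthetic Research Council"
        ],
        "objectives": "Link study records to routine records.",
        "reviewers": "Synthetic Ethics Committee"
      },
      "research": "Health and economic records held by public bodies may be accessed.",
      "withdrawal_procedure": "Write to the study office to withdraw at any time.",
      "data_flow_description": "Identifiers flow to the trusted third party only."
    }
  ],
  "extensions": {}
}
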