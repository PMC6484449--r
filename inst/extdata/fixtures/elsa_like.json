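{
  "form_id": "ELSA-18753",
  "study_name": "Exampleton Synthetic Cohort",
  "organizations": [
    {
      "organization_name": "University of Mocktown",
      "ethics_approval_reference": "REC-3954",
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
        "email": "subject128@example.invalid",
        "location": "Stubbington",
        "nationality": "Exampleland"
      },
      "date_of_birth": "1956-03-28",
      "signature": {
        "signed": true,
        "date": "2016-07-14"
      },
      "confirmation_of_understanding": true
    },
    {
      "id": "p2",
      "full_name": "Elia Mockwell",
      "role": "interviewer",
      "kind": "professional",
      "signature": {
        "signed": true,
        "date": "2016-07-14"
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
      "method_of_collection": "interviewer_administered"
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
      "method_of_collection": "interviewer_administered"
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
      "health_temporal": [
        "past"
      ],
      "future_contact": true
    },
    {
      "category": "economic",
      "granted": true,
      "economic_parts": [
        "benefits_claims",
        "ni_contributions",
        "tax"
      ],
      "future_contact": false
    }
  ],
  "date_of_completion": "2016-07-14",
  "instructions_for_next_steps": "Keep one copy; return the other copy to the study office.",
  "informational_documents": [],
  "extensions": {}
}
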