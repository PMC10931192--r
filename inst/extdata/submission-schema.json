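{
  "title": "Integrated-evidence variant submission payload",
  "description": "Document structure for programmatic archive submission of one germline SDHx variant with its integrated framework evidence. Modeled on the public NCBI ClinVar API submission layout (variant set via HGVS, condition set by name, observedIn block, free-text evidence comment). Payloads carry the framework category and comment as structured evidence text and never assert a clinical-significance reclassification. No protected health information is permitted in any field.",
  "type": "object",
  "required": ["variantSet", "conditionSet", "observedIn", "evidence", "submitter"],
  "properties": {
    "variantSet": {
      "type": "object",
      "required": ["gene", "hgvs"],
      "properties": {
        "gene": {"type": "string"},
        "hgvs": {"type": "string"}
      }
    },
    "conditionSet": {
      "type": "object",
      "required": ["name"],
      "properties": {
        "name": {"type": "string"}
      }
    },
    "observedIn": {
      "type": "object",
      "required": ["alleleOrigin", "affectedStatus", "collectionMethod", "numberOfIndividuals"],
      "properties": {
        "alleleOrigin": {"type": "string"},
        "affectedStatus": {"type": "string"},
        "collectionMethod": {"type": "string"},
        "numberOfIndividuals": {"type": "number"}
      }
    },
    "evidence": {
      "type": "object",
      "required": ["code", "category", "comment", "evidenceSummary"],
      "properties": {
        "code": {"type": "string"},
        "category": {"type": "string"},
        "comment": {"type": "string"},
        "evidenceSummary": {"type": "string"}
      }
    },
    "submitter": {
      "type": "object",
      "required": ["organization", "rulebookVersion", "mode"],
      "properties": {
        "organization": {"type": "string"},
        "rulebookVersion": {"type": "string"},
        "mode": {"type": "string"}
      }
    }
  }
}
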