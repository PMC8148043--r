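{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "pwsasdx diagnostic report",
  "type": "object",
  "required": ["specimen_id", "syndrome", "mechanism", "parental_origin",
               "label", "evidence", "caveats", "modules", "thresholds"],
  "properties": {
    "specimen_id": {"type": "string"},
    "syndrome": {"type": "string", "enum": ["PWS", "AS", "none", "indeterminate"]},
    "mechanism": {"type": "string"},
    "parental_origin": {"type": "string", "enum": ["paternal", "maternal", "n/a"]},
    "label": {"type": "string"},
    "evidence": {"type": "array", "items": {"type": "string"}},
    "caveats": {"type": "array", "items": {"type": "string"}},
    "modules": {"type": "object"},
    "thresholds": {"type": "object"}
  }
}
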