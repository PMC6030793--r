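{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "polyhybrid pipeline summary",
  "type": "object",
  "required": ["seed", "cutoffs"],
  "properties": {
    "seed": {"type": "integer"},
    "cutoffs": {
      "type": "object",
      "required": ["deg_fdr", "category_fdr", "lfc", "mpv_lfc"]
    },
    "coexpressed": {"type": "object"},
    "deg": {"type": "object"},
    "eld": {"type": "object"},
    "eld_asymmetry": {"type": "object"},
    "eld_inheritance": {"type": "object"},
    "dosage": {"type": "object"},
    "ortho": {"type": "object"}
  }
}
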