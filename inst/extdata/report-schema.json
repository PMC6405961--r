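{
  "title": "seroscan report",
  "required": ["rows", "summaries", "provenance"],
  "row_fields": ["id", "genus", "species", "class", "score_Sn1",
                 "score_Sn2", "score_Sn3", "margin", "version", "gene",
                 "name", "a_end", "module_spans", "flag"]
}
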