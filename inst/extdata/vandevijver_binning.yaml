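# Clinical-parameter categorizations for the van de Vijver breast cancer
# cohort (295 subjects): all parameters are already nominal, so every column
# passes through unchanged. Listed explicitly for documentation.
columns:
  metastasis:
    kind: passthrough
  positive lymph nodes:
    kind: passthrough
  event death:
    kind: passthrough
  estrogen receptor:
    kind: passthrough
  National Institute Health criteria:
    kind: passthrough
  St. Gallen consensus criteria:
    kind: passthrough
  conservative flag:
    kind: passthrough
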