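# Approximate SERCA1a (author numbering) domain partition used as the
# package default.  Block boundaries are a documented repository choice;
# adjust per study as needed.
# Domain keys are quoted: bare N/Y are YAML 1.1 booleans.
domains:
  "A":  [[1, 43], [124, 242]]
  "TM": [[44, 123], [243, 329], [740, 994]]
  "P":  [[330, 359], [601, 739]]
  "N":  [[360, 600]]
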