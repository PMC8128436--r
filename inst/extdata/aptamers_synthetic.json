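{
  "note": "Synthetic stand-in aptamer definitions. Each entry carries the literature core recognition motif of the named aptamer inside a simplified closing-stem/bulge/inner-hairpin architecture constructed for this package; these are NOT the published full-length aptamer sequences. Structures are annotated dot-brackets, not predicted folds. binding_bulge is a 1-based inclusive range.",
  "aptamers": [
    {
      "name": "theophylline",
      "full_sequence": "GGCAAUACCAGCCGAAAGGCCCUUGGCAGUGCC",
      "full_structure": "((((.......((....))..........))))",
      "binding_bulge": [5, 11],
      "allowed_positions": ["I", "II"]
    },
    {
      "name": "tetracycline",
      "full_sequence": "GGCACAAAACAUACCAGAUGAAAAUCUGGAGAGGUGUGCC",
      "full_structure": "(((((..........((((....))))........)))))",
      "binding_bulge": [6, 15],
      "allowed_positions": ["I", "II"]
    },
    {
      "name": "neomycin",
      "full_sequence": "GGCUGCUUGUCCUUUAAUGGUCCCAGCC",
      "full_structure": "(((((..................)))))",
      "binding_bulge": [6, 23],
      "allowed_positions": ["I", "II"]
    },
    {
      "name": "chloramphenicol",
      "full_sequence": "GGAGCUUCAGGAGUGCUCGAAAGAGCAAGGUUGCUCC",
      "full_structure": "(((((.........((((....))))......)))))",
      "binding_bulge": [6, 14],
      "allowed_positions": ["I", "II"]
    },
    {
      "name": "folinic_acid",
      "full_sequence": "GGACGAGUGGAAGGAUCCGUGCAAACGGAGUAAGCGUCC",
      "full_structure": "(((((...........((((....))))......)))))",
      "binding_bulge": [6, 16],
      "allowed_positions": ["I", "II"]
    }
  ]
}
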