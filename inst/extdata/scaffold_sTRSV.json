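{
  "name": "sTRSV",
  "note": "Literature-derived sTRSV hammerhead ribozyme scaffold (satellite RNA of tobacco ringspot virus). The 5' and 3' spacer blocks here are the stem-III closing arms of the minimal 52-nt ribozyme; edit them to add transcript-context spacers.",
  "segments": {
    "spacer5": "GCUGUC",
    "stem1_5p": "ACCGGA",
    "stem1_3p": "UCCGGU",
    "core": "CUGAUGA",
    "stem2_5p": "GUCC",
    "stem2_3p": "GGAC",
    "core3": "GAAA",
    "spacer3": "CAGC"
  },
  "default_stem1_len": 6,
  "default_stem2_len": 4,
  "native_loops": {
    "loop1": "UGUGCUU",
    "loop2": "GUGA"
  },
  "native_full_sequence": "GCUGUCACCGGAUGUGCUUUCCGGUCUGAUGAGUCCGUGAGGACGAAACAGC"
}
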