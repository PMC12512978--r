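{
  "comment": "Per-hemisphere subnucleus counts for six published thalamic atlases as distributed with Lead-DBS. Counts are recorded as per-hemisphere values (the published breakdown does not state whether totals are bilateral; this fixture assumes per-hemisphere).",
  "atlases": [
    {"atlas": "Jakab 2008",      "abbreviation": "Jak08", "total": 32, "motor": 6, "sensory": 4},
    {"atlas": "Ewert 2017",      "abbreviation": "Ewt17", "total": 46, "motor": 5, "sensory": 9},
    {"atlas": "Ilinsky 2017",    "abbreviation": "Iln17", "total": 15, "motor": 3, "sensory": 2},
    {"atlas": "Iglesias 2018",   "abbreviation": "Igl18", "total": 23, "motor": 4, "sensory": 1},
    {"atlas": "Saranathan 2019", "abbreviation": "Sar19", "total": 10, "motor": 4, "sensory": 1},
    {"atlas": "Ding 2020",       "abbreviation": "Dng20", "total": 13, "motor": 2, "sensory": 3}
  ]
}
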