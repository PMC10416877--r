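{
  "version": 1,
  "comment": "Default screening condition grids per model; values are the frequently adopted experimental conditions the deployed models were exposed to most. The oncogene/target field is derived from the G4 sequence, not an independent factor.",
  "sequence_targets": {
    "AGGGTTAGGGTTAGGGTTAGGG": "hTel",
    "GGGTTAGGGTTAGGGTTAGGG": "hTel",
    "TGAGGGTGGGTAGGGTGGGTAA": "cMYC",
    "GGGAGGGCGCTGGGAGGAGGG": "cKIT1",
    "GGGCGGGCGCGAGGGAGGGG": "cKIT2",
    "AGGGCGGTGTGGGAAGAGGGAAGAGGGGGAGG": "KRAS"
  },
  "models": {
    "selectivity": {
      "endpoint": "dTm",
      "fields": {
        "sequence": [
          "AGGGTTAGGGTTAGGGTTAGGG",
          "GGGTTAGGGTTAGGGTTAGGG",
          "TGAGGGTGGGTAGGGTGGGTAA",
          "GGGAGGGCGCTGGGAGGAGGG",
          "GGGCGGGCGCGAGGGAGGGG",
          "AGGGCGGTGTGGGAAGAGGGAAGAGGGGGAGG"
        ],
        "buffer": [
          "KCl 10 mM LiCl 90 mM Lithium Cacodylate (10 mM)",
          "NaCl 100 mM Lithium Cacodylate (10 mM)",
          "KCl 100 mM Lithium Cacodylate (10 mM)"
        ],
        "assay": ["FRET melting"]
      },
      "derived": {"oncogene": "sequence"}
    },
    "interaction": {
      "endpoint": "Kd",
      "fields": {
        "sequence": [
          "AGGGTTAGGGTTAGGGTTAGGG",
          "GGGTTAGGGTTAGGGTTAGGG",
          "TGAGGGTGGGTAGGGTGGGTAA",
          "GGGAGGGCGCTGGGAGGAGGG",
          "GGGCGGGCGCGAGGGAGGGG",
          "AGGGCGGTGTGGGAAGAGGGAAGAGGGGGAGG"
        ],
        "buffer": [
          "KCl 100 mM Lithium Cacodylate (10 mM)",
          "NaCl 35 mM KCl 50 mM Tween20 0.05% HEPES (10 mM)",
          "NaCl 100 mM Tris-HCl (50 mM)",
          "KCl 100 mM Tris-HCl (10 mM)"
        ]
      },
      "derived": {"oncogene": "sequence"}
    },
    "stabilization": {
      "endpoint": "dTm",
      "fields": {
        "sequence": [
          "AGGGTTAGGGTTAGGGTTAGGG",
          "GGGTTAGGGTTAGGGTTAGGG",
          "TGAGGGTGGGTAGGGTGGGTAA",
          "GGGAGGGCGCTGGGAGGAGGG",
          "GGGCGGGCGCGAGGGAGGGG",
          "AGGGCGGTGTGGGAAGAGGGAAGAGGGGGAGG"
        ],
        "buffer": [
          "KCl 10 mM LiCl 90 mM Lithium Cacodylate (10 mM)",
          "NaCl 10 mM LiCl 90 mM Lithium Cacodylate (10 mM)"
        ],
        "assay": ["FRET melting"],
        "lgr": ["5", "10"]
      },
      "derived": {"oncogene": "sequence"}
    },
    "cytotoxicity": {
      "endpoint": "IC50",
      "fields": {
        "cell_line": ["HELA", "A549", "MCF7", "A375", "HCT116"],
        "exposure_time": ["48", "72"],
        "assay": ["MTT"]
      }
    }
  }
}
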