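{
  "score_max": 50,
  "entries": [
    {"gene_id": "PER3",   "entrez_id": "8863",   "direction": "HIGH", "weight": 5.100},
    {"gene_id": "PRSS53", "entrez_id": "339105", "direction": "HIGH", "weight": 4.569},
    {"gene_id": "KIFC3",  "entrez_id": "3801",   "direction": "HIGH", "weight": 3.328},
    {"gene_id": "TYRP1",  "entrez_id": "7306",   "direction": "HIGH", "weight": 2.078},
    {"gene_id": "BTBD16", "entrez_id": "118663", "direction": "HIGH", "weight": 1.337},
    {"gene_id": "CHRNA3", "entrez_id": "1136",   "direction": "HIGH", "weight": 1.047},
    {"gene_id": "LGR4",   "entrez_id": "55366",  "direction": "LOW",  "weight": 4.597},
    {"gene_id": "LYAR",   "entrez_id": "55646",  "direction": "LOW",  "weight": 4.439},
    {"gene_id": "CCT2",   "entrez_id": "10576",  "direction": "LOW",  "weight": 4.404},
    {"gene_id": "CCNE1",  "entrez_id": "898",    "direction": "LOW",  "weight": 4.226},
    {"gene_id": "PRMT1",  "entrez_id": "3276",   "direction": "LOW",  "weight": 4.155},
    {"gene_id": "TESK2",  "entrez_id": "10420",  "direction": "LOW",  "weight": 4.060},
    {"gene_id": "LYPD6",  "entrez_id": "130574", "direction": "LOW",  "weight": 3.960},
    {"gene_id": "F2RL1",  "entrez_id": "2150",   "direction": "LOW",  "weight": 1.465},
    {"gene_id": "CEP55",  "entrez_id": "55165",  "direction": "LOW",  "weight": 1.061},
    {"gene_id": "SIAE",   "entrez_id": "54414",  "direction": "LOW",  "weight": 0.174}
  ]
}
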