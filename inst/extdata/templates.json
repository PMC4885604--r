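[
  {
    "id": "t_gg_pos", "covered": true,
    "sentences": ["{Gene:1} directly {POS:1} {Gene:2} in tumor cells."],
    "relations": [
      {"sentence": 1, "subject": "Gene:1", "trigger": "POS:1", "object": "Gene:2"}
    ]
  },
  {
    "id": "t_gg_neg", "covered": true,
    "sentences": ["{Gene:1} markedly {NEG:1} {Gene:2}."],
    "relations": [
      {"sentence": 1, "subject": "Gene:1", "trigger": "NEG:1", "object": "Gene:2"}
    ]
  },
  {
    "id": "t_gg_neu", "covered": true,
    "sentences": ["{Gene:1} {NEU:1} the expression of {Gene:2}."],
    "relations": [
      {"sentence": 1, "subject": "Gene:1", "trigger": "NEU:1", "object": "Gene:2"}
    ]
  },
  {
    "id": "t_mir_g", "covered": true,
    "sentences": ["Overexpression of {MicroRNA:1} {NEG:1} {Gene:1}."],
    "relations": [
      {"sentence": 1, "subject": "MicroRNA:1", "trigger": "NEG:1", "object": "Gene:1"}
    ]
  },
  {
    "id": "t_g_mir", "covered": true,
    "sentences": ["{Gene:1} transcriptionally {POS:1} {MicroRNA:1}."],
    "relations": [
      {"sentence": 1, "subject": "Gene:1", "trigger": "POS:1", "object": "MicroRNA:1"}
    ]
  },
  {
    "id": "t_gm_pos", "covered": true,
    "sentences": ["{Gene:1} {POS:1} {NeoplasmMetastasis:1} in vitro."],
    "relations": [
      {"sentence": 1, "subject": "Gene:1", "trigger": "POS:1", "object": "NeoplasmMetastasis:1"}
    ]
  },
  {
    "id": "t_gm_move", "covered": true,
    "sentences": ["{Gene:1} potently {NEG:1} {CellMovement:1}."],
    "relations": [
      {"sentence": 1, "subject": "Gene:1", "trigger": "NEG:1", "object": "CellMovement:1"}
    ]
  },
  {
    "id": "t_gm_adh", "covered": true,
    "sentences": ["Ectopic {MicroRNA:1} {NEG:1} {CellAdhesion:1} in epithelial cells."],
    "relations": [
      {"sentence": 1, "subject": "MicroRNA:1", "trigger": "NEG:1", "object": "CellAdhesion:1"}
    ]
  },
  {
    "id": "t_gm_cyto", "covered": true,
    "sentences": ["{Gene:1} {POS:1} {Cytoskeleton:1} formation."],
    "relations": [
      {"sentence": 1, "subject": "Gene:1", "trigger": "POS:1", "object": "Cytoskeleton:1"}
    ]
  },
  {
    "id": "t_gn_pos", "covered": true,
    "sentences": ["{Gene:1} {POS:1} the growth of {Neoplasms:1}."],
    "relations": [
      {"sentence": 1, "subject": "Gene:1", "trigger": "POS:1", "object": "Neoplasms:1"}
    ]
  },
  {
    "id": "t_gn_neg", "covered": true,
    "sentences": ["Enforced expression of {MicroRNA:1} {NEG:1} {Neoplasms:1} progression."],
    "relations": [
      {"sentence": 1, "subject": "MicroRNA:1", "trigger": "NEG:1", "object": "Neoplasms:1"}
    ]
  },
  {
    "id": "t_nm_organ", "covered": true,
    "sentences": ["{Neoplasms:1} frequently {MET:1} to the {Organ:1}."],
    "relations": [
      {"sentence": 1, "subject": "Neoplasms:1", "trigger": "MET:1", "object": "Organ:1"}
    ]
  },
  {
    "id": "t_nm_tissue", "covered": true,
    "sentences": ["{Neoplasms:1} eventually {MET:1} into the {Tissues:1}."],
    "relations": [
      {"sentence": 1, "subject": "Neoplasms:1", "trigger": "MET:1", "object": "Tissues:1"}
    ]
  },
  {
    "id": "t_chain_ggm", "covered": true,
    "sentences": [
      "{Gene:1} strongly {POS:1} {Gene:2}.",
      "{Gene:2} then {POS:2} {NeoplasmMetastasis:1}."
    ],
    "relations": [
      {"sentence": 1, "subject": "Gene:1", "trigger": "POS:1", "object": "Gene:2"},
      {"sentence": 2, "subject": "Gene:2", "trigger": "POS:2", "object": "NeoplasmMetastasis:1"}
    ]
  },
  {
    "id": "t_chain_ggno", "covered": true,
    "sentences": [
      "{Gene:1} {POS:1} {Gene:2} in this model.",
      "{Gene:2} {POS:2} the progression of {Neoplasms:1}.",
      "{Neoplasms:1} subsequently {MET:1} to the {Organ:1}."
    ],
    "relations": [
      {"sentence": 1, "subject": "Gene:1", "trigger": "POS:1", "object": "Gene:2"},
      {"sentence": 2, "subject": "Gene:2", "trigger": "POS:2", "object": "Neoplasms:1"},
      {"sentence": 3, "subject": "Neoplasms:1", "trigger": "MET:1", "object": "Organ:1"}
    ]
  },
  {
    "id": "t_d_cohort", "covered": false,
    "sentences": ["Patients with {Neoplasms:1} were enrolled in this retrospective study."],
    "relations": []
  },
  {
    "id": "t_d_expr", "covered": false,
    "sentences": ["Expression of {Gene:1} was examined in {Tissues:1} specimens."],
    "relations": []
  },
  {
    "id": "t_d_prose", "covered": false,
    "sentences": ["These findings warrant further validation in independent cohorts."],
    "relations": []
  },
  {
    "id": "t_d_more", "covered": false,
    "sentences": ["{Gene:1} expression was observed more often in advanced cases."],
    "relations": []
  },
  {
    "id": "t_d_mir", "covered": false,
    "sentences": ["The prognostic significance of {MicroRNA:1} remains unclear."],
    "relations": []
  }
]
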