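[
  {
    "rule_id": "gg_pos",
    "slots": ["GENE", "POSITIVE_REG", "GENE"],
    "subject_slot": 1, "trigger_slot": 2, "object_slot": 3,
    "relation_type": "positive_regulation", "max_gap": 3
  },
  {
    "rule_id": "gg_neg",
    "slots": ["GENE", "NEGATIVE_REG", "GENE"],
    "subject_slot": 1, "trigger_slot": 2, "object_slot": 3,
    "relation_type": "negative_regulation", "max_gap": 3
  },
  {
    "rule_id": "gg_neu",
    "slots": ["GENE", "NEUTRAL_REG", "GENE"],
    "subject_slot": 1, "trigger_slot": 2, "object_slot": 3,
    "relation_type": "neutral_regulation", "max_gap": 3
  },
  {
    "rule_id": "gm_pos",
    "slots": ["GENE", "POSITIVE_REG", "METASTASIS"],
    "subject_slot": 1, "trigger_slot": 2, "object_slot": 3,
    "relation_type": "positive_regulation", "max_gap": 3
  },
  {
    "rule_id": "gm_neg",
    "slots": ["GENE", "NEGATIVE_REG", "METASTASIS"],
    "subject_slot": 1, "trigger_slot": 2, "object_slot": 3,
    "relation_type": "negative_regulation", "max_gap": 3
  },
  {
    "rule_id": "gm_neu",
    "slots": ["GENE", "NEUTRAL_REG", "METASTASIS"],
    "subject_slot": 1, "trigger_slot": 2, "object_slot": 3,
    "relation_type": "neutral_regulation", "max_gap": 3
  },
  {
    "rule_id": "gn_pos",
    "slots": ["GENE", "POSITIVE_REG", "NEOPLASMS"],
    "subject_slot": 1, "trigger_slot": 2, "object_slot": 3,
    "relation_type": "positive_regulation", "max_gap": 3
  },
  {
    "rule_id": "gn_neg",
    "slots": ["GENE", "NEGATIVE_REG", "NEOPLASMS"],
    "subject_slot": 1, "trigger_slot": 2, "object_slot": 3,
    "relation_type": "negative_regulation", "max_gap": 3
  },
  {
    "rule_id": "gn_neu",
    "slots": ["GENE", "NEUTRAL_REG", "NEOPLASMS"],
    "subject_slot": 1, "trigger_slot": 2, "object_slot": 3,
    "relation_type": "neutral_regulation", "max_gap": 3
  },
  {
    "rule_id": "nm_organ",
    "slots": ["NEOPLASMS", "METASTASIS_TRIGGER", "ORGAN"],
    "subject_slot": 1, "trigger_slot": 2, "object_slot": 3,
    "relation_type": "metastasis", "max_gap": 3
  },
  {
    "rule_id": "nm_tissue",
    "slots": ["NEOPLASMS", "METASTASIS_TRIGGER", "TISSUES"],
    "subject_slot": 1, "trigger_slot": 2, "object_slot": 3,
    "relation_type": "metastasis", "max_gap": 3
  }
]
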