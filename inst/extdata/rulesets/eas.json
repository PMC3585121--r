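{
  "pathway": "EAS",
  "description": "Ergot alkaloid biosynthesis: ergoline skeleton (chanoclavine-I, agroclavine) and decorations to lysergyl amides and ergopeptines.",
  "catalog": ["dmaW", "easF", "easE", "easC", "easD", "easA", "easG", "cloA",
              "easH", "easO", "easP", "lpsA", "lpsB", "lpsC"],
  "options": {"ec_oxidase": "cloA", "easA_variant": "agroclavine"},
  "products": [
    {"id": "CC", "label": "chanoclavine-I",
     "requires": ["dmaW", "easF", "easE", "easC"], "parent": null},
    {"id": "agroclavine", "label": "agroclavine",
     "requires": ["easD", "easA", "easG"], "parent": "CC"},
    {"id": "EC", "label": "elymoclavine",
     "requires": ["cloA"], "parent": "agroclavine",
     "oxidase_option": true},
    {"id": "lysergic_acid", "label": "lysergic acid",
     "requires": ["cloA"], "parent": "EC"},
    {"id": "EN", "label": "ergonovine",
     "requires": ["lpsB", "lpsC"], "parent": "lysergic_acid"},
    {"id": "LAH", "label": "lysergic acid alpha-hydroxyethylamide",
     "requires": ["easO", "easP"], "parent": "EN"},
    {"id": "ergopeptine", "label": "ergopeptine",
     "requires": ["lpsA", "lpsB", "easH"], "parent": "lysergic_acid"}
  ]
}
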