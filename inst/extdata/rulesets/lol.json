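{
  "pathway": "LOL",
  "description": "Loline alkaloid biosynthesis: NANL is the first fully cyclized intermediate; decorations lead via NML to NFL.",
  "catalog": ["lolF", "lolC", "lolD", "lolO", "lolA", "lolU", "lolP",
              "lolT", "lolE", "lolN", "lolM"],
  "options": {},
  "products": [
    {"id": "AcAP", "label": "1-acetamidopyrrolizidine",
     "requires": ["lolF", "lolC", "lolD", "lolA", "lolU", "lolT", "lolE"],
     "parent": null},
    {"id": "NANL", "label": "N-acetylnorloline",
     "requires": ["lolO"], "parent": "AcAP"},
    {"id": "NML", "label": "N-methylloline",
     "requires": ["lolN", "lolM"], "parent": "NANL"},
    {"id": "NFL", "label": "N-formylloline",
     "requires": ["lolP"], "parent": "NML"}
  ]
}
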