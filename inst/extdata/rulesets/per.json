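{
  "pathway": "PER",
  "description": "Peramine biosynthesis by the multifunctional perA gene; the perA form lacking the terminal reductase domain (delta_r) does not yield peramine.",
  "catalog": ["perA"],
  "options": {},
  "products": [
    {"id": "PER", "label": "peramine",
     "requires": ["perA"], "parent": null}
  ]
}
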