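{
  "pathway": "IDT",
  "description": "Indole-diterpene biosynthesis: paspaline core and decorations to paxilline-type, terpendole-type and lolitrem products.",
  "catalog": ["idtG", "idtM", "idtB", "idtC", "idtS", "idtP", "idtQ",
              "idtF", "idtK", "idtE", "idtJ"],
  "aliases": {"ltmG": "idtG", "ltmM": "idtM", "ltmB": "idtB", "ltmC": "idtC",
              "ltmS": "idtS", "ltmP": "idtP", "ltmQ": "idtQ", "ltmF": "idtF",
              "ltmK": "idtK", "ltmE": "idtE", "ltmJ": "idtJ"},
  "options": {"require_idtS": true},
  "products": [
    {"id": "paspaline", "label": "paspaline",
     "requires": ["idtG", "idtM", "idtB", "idtC"], "parent": null,
     "co_required_option": "idtS"},
    {"id": "PAX", "label": "paxilline",
     "requires": ["idtP", "idtQ"], "parent": "paspaline"},
    {"id": "TDK", "label": "terpendole K",
     "requires": ["idtF", "idtK"], "parent": "PAX"},
    {"id": "LTM", "label": "lolitrem B",
     "requires": ["idtE", "idtJ"], "parent": "TDK"}
  ]
}
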