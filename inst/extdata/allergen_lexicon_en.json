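{
  "name": "en-default",
  "version": "1.0",
  "allergens": {
    "gluten_cereals": {
      "canonical_terms": ["gluten", "wheat", "rye", "barley", "oats", "oat", "spelt", "kamut"],
      "derivative_terms": ["semolina", "durum", "malt", "couscous", "bulgur", "wheat flour", "barley malt extract", "oat flakes", "wholegrain wheat", "triticale"],
      "exclusion_patterns": ["gluten[ -]free", "free from gluten", "χωρισ γλουτενη"],
      "e_number_ranges": []
    },
    "crustaceans": {
      "canonical_terms": ["crustaceans", "crustacean", "shrimp", "shrimps", "prawn", "prawns", "crab", "lobster", "crayfish"],
      "derivative_terms": [],
      "exclusion_patterns": [],
      "e_number_ranges": []
    },
    "eggs": {
      "canonical_terms": ["egg", "eggs"],
      "derivative_terms": ["egg white", "egg yolk", "egg powder", "albumin", "ovalbumin", "lysozyme"],
      "exclusion_patterns": ["egg[ -]free"],
      "e_number_ranges": []
    },
    "fish": {
      "canonical_terms": ["fish"],
      "derivative_terms": ["anchovy", "anchovies", "cod", "tuna", "salmon", "sardine", "sardines", "fish gelatine", "fish oil"],
      "exclusion_patterns": [],
      "e_number_ranges": []
    },
    "peanuts": {
      "canonical_terms": ["peanut", "peanuts"],
      "derivative_terms": ["groundnut", "groundnuts", "arachis oil", "peanut butter"],
      "exclusion_patterns": ["peanut[ -]free"],
      "e_number_ranges": []
    },
    "soybeans": {
      "canonical_terms": ["soy", "soya", "soybean", "soybeans"],
      "derivative_terms": ["soy lecithin", "soya lecithin", "tofu", "edamame", "soy protein", "soy sauce", "miso"],
      "exclusion_patterns": ["soy[ -]free", "soya[ -]free"],
      "e_number_ranges": []
    },
    "milk": {
      "canonical_terms": ["milk"],
      "derivative_terms": ["whey", "casein", "caseinate", "lactose", "cream", "yogurt", "yoghurt", "cheese", "butter", "buttermilk", "butterfat", "curd", "milk solids", "skimmed milk powder"],
      "exclusion_patterns": ["lactose[ -]free", "dairy[ -]free", "milk[ -]free", "χωρισ λακτοζη"],
      "e_number_ranges": []
    },
    "tree_nuts": {
      "canonical_terms": ["nuts", "tree nuts", "almond", "almonds", "hazelnut", "hazelnuts", "walnut", "walnuts", "cashew", "cashews", "pistachio", "pistachios", "pecan", "pecans", "macadamia", "brazil nuts"],
      "derivative_terms": ["praline", "marzipan", "nut paste", "nougat"],
      "exclusion_patterns": ["nut[ -]free"],
      "e_number_ranges": []
    },
    "celery": {
      "canonical_terms": ["celery"],
      "derivative_terms": ["celeriac", "celery salt", "celery seed"],
      "exclusion_patterns": [],
      "e_number_ranges": []
    },
    "mustard": {
      "canonical_terms": ["mustard"],
      "derivative_terms": ["mustard seed", "mustard flour", "dijon mustard"],
      "exclusion_patterns": [],
      "e_number_ranges": []
    },
    "sesame": {
      "canonical_terms": ["sesame", "sesame seeds", "sesame seed"],
      "derivative_terms": ["tahini", "sesame oil", "sesame paste"],
      "exclusion_patterns": [],
      "e_number_ranges": []
    },
    "sulphites": {
      "canonical_terms": ["sulphites", "sulfites", "sulphite", "sulfite", "sulphur dioxide", "sulfur dioxide"],
      "derivative_terms": ["sodium metabisulphite", "sodium metabisulfite", "potassium metabisulphite", "sodium sulphite", "sodium bisulphite"],
      "exclusion_patterns": ["sulphite[ -]free", "sulfite[ -]free"],
      "e_number_ranges": [[220, 228]]
    },
    "lupin": {
      "canonical_terms": ["lupin", "lupine"],
      "derivative_terms": ["lupin flour", "lupin protein"],
      "exclusion_patterns": [],
      "e_number_ranges": []
    },
    "mollusks": {
      "canonical_terms": ["mollusks", "molluscs", "mollusc", "mussel", "mussels", "oyster", "oysters", "squid", "octopus", "clam", "clams", "scallop", "scallops", "snails"],
      "derivative_terms": ["cuttlefish"],
      "exclusion_patterns": [],
      "e_number_ranges": []
    }
  },
  "trigger_phrases": [
    "may contain traces of",
    "may contain trace of",
    "may contain",
    "traces of",
    "possible traces of",
    "may be present",
    "manufactured in a facility that also processes",
    "manufactured in a facility that also processed",
    "produced in a facility that also handles",
    "made in a facility that also processes",
    "produced on shared equipment",
    "μπορει να περιεχει ιχνη",
    "ιχνη απο",
    "ενδεχεται να περιεχει"
  ],
  "contains_statement_phrases": ["contains", "περιεχει"]
}
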