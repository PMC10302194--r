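{
  "name": "el-demo",
  "version": "1.0",
  "allergens": {
    "gluten_cereals": {
      "canonical_terms": ["γλουτενη", "σιταρι", "κριθαρι", "σικαλη", "βρωμη"],
      "derivative_terms": ["σιμιγδαλι", "αλευρι σιταριου", "βυνη"],
      "exclusion_patterns": ["χωρισ γλουτενη"],
      "e_number_ranges": []
    },
    "crustaceans": {
      "canonical_terms": ["καρκινοειδη", "γαριδα", "γαριδεσ", "καβουρι", "αστακοσ"],
      "derivative_terms": [],
      "exclusion_patterns": [],
      "e_number_ranges": []
    },
    "eggs": {
      "canonical_terms": ["αυγο", "αυγα"],
      "derivative_terms": ["ασπραδι αυγου", "κροκοσ αυγου"],
      "exclusion_patterns": [],
      "e_number_ranges": []
    },
    "fish": {
      "canonical_terms": ["ψαρι", "ψαρια"],
      "derivative_terms": ["αντζουγια", "τονοσ", "σολομοσ"],
      "exclusion_patterns": [],
      "e_number_ranges": []
    },
    "peanuts": {
      "canonical_terms": ["αραπικα φιστικια", "αραπικο φιστικι"],
      "derivative_terms": ["φυστικοβουτυρο"],
      "exclusion_patterns": [],
      "e_number_ranges": []
    },
    "soybeans": {
      "canonical_terms": ["σογια"],
      "derivative_terms": ["λεκιθινη σογιασ", "πρωτεϊνη σογιασ", "τοφου"],
      "exclusion_patterns": ["χωρισ σογια"],
      "e_number_ranges": []
    },
    "milk": {
      "canonical_terms": ["γαλα"],
      "derivative_terms": ["οροσ γαλακτοσ", "καζεϊνη", "λακτοζη", "τυρι", "γιαουρτι", "βουτυρο", "κρεμα γαλακτοσ"],
      "exclusion_patterns": ["χωρισ λακτοζη", "χωρισ γαλα"],
      "e_number_ranges": []
    },
    "tree_nuts": {
      "canonical_terms": ["ξηροι καρποι", "ξηρουσ καρπουσ", "αμυγδαλα", "φουντουκια", "καρυδια", "κασιουσ", "φιστικια αιγινησ"],
      "derivative_terms": ["πραλινα", "παστα φουντουκιου"],
      "exclusion_patterns": [],
      "e_number_ranges": []
    },
    "celery": {
      "canonical_terms": ["σελινο"],
      "derivative_terms": ["σελινοριζα"],
      "exclusion_patterns": [],
      "e_number_ranges": []
    },
    "mustard": {
      "canonical_terms": ["μουσταρδα", "σιναπι"],
      "derivative_terms": [],
      "exclusion_patterns": [],
      "e_number_ranges": []
    },
    "sesame": {
      "canonical_terms": ["σουσαμι"],
      "derivative_terms": ["ταχινι", "σησαμελαιο"],
      "exclusion_patterns": [],
      "e_number_ranges": []
    },
    "sulphites": {
      "canonical_terms": ["θειωδη", "διοξειδιο του θειου"],
      "derivative_terms": [],
      "exclusion_patterns": [],
      "e_number_ranges": [[220, 228]]
    },
    "lupin": {
      "canonical_terms": ["λουπινο"],
      "derivative_terms": ["αλευρι λουπινου"],
      "exclusion_patterns": [],
      "e_number_ranges": []
    },
    "mollusks": {
      "canonical_terms": ["μαλακια", "μυδια", "καλαμαρι", "χταποδι", "στρειδια"],
      "derivative_terms": [],
      "exclusion_patterns": [],
      "e_number_ranges": []
    }
  },
  "trigger_phrases": [
    "μπορει να περιεχει ιχνη",
    "ιχνη απο",
    "ενδεχεται να περιεχει",
    "παραγεται σε μοναδα που επεξεργαζεται επισησ"
  ],
  "contains_statement_phrases": ["περιεχει"]
}
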