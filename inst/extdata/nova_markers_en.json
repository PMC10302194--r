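{
  "name": "en-default",
  "version": "1.0",
  "marker_classes": {
    "sweeteners": {
      "terms": ["sweetener", "sweeteners", "aspartame", "sucralose", "acesulfame k", "acesulfame", "saccharin", "cyclamate", "steviol glycosides", "stevia", "xylitol", "maltitol", "glucose syrup", "glucose-fructose syrup", "fructose syrup", "high fructose corn syrup", "invert sugar syrup", "maltodextrin", "dextrose"],
      "e_number_ranges": [[950, 969]]
    },
    "flavourings": {
      "terms": ["flavouring", "flavourings", "flavoring", "flavorings", "natural flavour", "natural flavours", "natural flavor", "natural flavors", "aroma", "aromas", "vanillin"],
      "e_number_ranges": []
    },
    "flavour_enhancers": {
      "terms": ["flavour enhancer", "flavour enhancers", "flavor enhancer", "flavor enhancers", "monosodium glutamate", "yeast extract"],
      "e_number_ranges": [[620, 650]]
    },
    "emulsifiers": {
      "terms": ["emulsifier", "emulsifiers", "lecithin", "lecithins", "mono- and diglycerides", "mono and diglycerides"],
      "e_number_ranges": [[322, 322], [470, 483]]
    },
    "thickeners": {
      "terms": ["thickener", "thickeners", "stabiliser", "stabilisers", "stabilizer", "stabilizers", "guar gum", "xanthan gum", "carrageenan", "pectin", "gellan gum", "locust bean gum", "carboxymethylcellulose", "modified starch", "gelling agent"],
      "e_number_ranges": [[400, 418], [425, 469]]
    },
    "bulking_agents": {
      "terms": ["bulking agent", "bulking agents", "polydextrose"],
      "e_number_ranges": [[1200, 1202], [1400, 1452]]
    },
    "antioxidants": {
      "terms": ["antioxidant", "antioxidants", "ascorbic acid", "tocopherols", "citric acid"],
      "e_number_ranges": [[300, 321], [330, 330]]
    },
    "protein_isolates": {
      "terms": ["protein isolate", "protein isolates", "protein concentrate", "protein concentrates", "pea protein", "whey protein", "hydrolysed protein", "hydrolyzed protein"],
      "e_number_ranges": []
    },
    "added_vitamins_minerals": {
      "terms": ["vitamin", "vitamins", "folic acid", "niacin", "riboflavin", "thiamin", "ferric pyrophosphate", "zinc oxide"],
      "e_number_ranges": []
    },
    "hydrolyzed_extruded": {
      "terms": ["hydrolysed", "hydrolyzed", "extruded", "hydrogenated", "interesterified", "invert sugar"],
      "e_number_ranges": []
    },
    "extracts": {
      "terms": ["extract", "extracts"],
      "e_number_ranges": []
    }
  },
  "culinary_terms": [
    "salt", "sea salt", "rock salt",
    "sugar", "cane sugar", "brown sugar", "icing sugar",
    "oil", "olive oil", "sunflower oil", "vegetable oil", "corn oil", "rapeseed oil", "palm oil", "coconut oil", "soybean oil",
    "starch", "corn starch", "cornflour", "potato starch",
    "butter", "lard", "animal fat",
    "honey"
  ],
  "water_terms": ["water", "νερο"],
  "subcategory_overrides": {
    "Egg imitation": 4,
    "Meat analogue": 4,
    "Prepared food product": 4,
    "Ready to eat food": 4,
    "Frozen, semi-ready meal": 4
  }
}
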