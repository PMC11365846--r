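{
  "_comment": "Example aquarisk configuration. The c_bg backgrounds below are SYNTHETIC site placeholders (the real site backgrounds are unpublished); replace them with measured values before interpreting RI.",
  "toxicity": {
    "metal": ["Fe", "Mn", "Cu", "Zn"],
    "c_bg": [20, 15, 5, 30]
  },
  "cai_numerator": "schoeller",
  "wqi_integration": "product"
}
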