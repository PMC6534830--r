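[
  {
    "name": "terminal-alkene enol",
    "smarts": "[OX2H1,OX1-][CX3]=[CX3;H2]",
    "note": "enol (or enolate) whose alkene carbon is a terminal CH2"
  },
  {
    "name": "geminal vinyl diol",
    "smarts": "[OX2H1,OX1-][CX3](=[CX3])[OX2H1,OX1-]",
    "note": "two hydroxyl/oxide groups on one alkene carbon; improbable carboxylic-acid (or carboxylate) tautomer"
  },
  {
    "name": "carbanion",
    "smarts": "[#6-]",
    "note": "negatively charged carbon"
  }
]
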