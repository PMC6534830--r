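[
  {"name": "alpha-amino-acid carboxylic acid", "smarts": "[NX3;H2][CX4][CX3](=O)[OX2H1]",
   "site": 5, "mean_pka": 2.3, "pka_sd": 0.5, "prot_charge": 0, "deprot_charge": -1},
  {"name": "alpha-amino-acid amine", "smarts": "[NX3;H2][CX4][CX3](=O)[OX2]",
   "site": 1, "mean_pka": 9.6, "pka_sd": 0.5, "prot_charge": 1, "deprot_charge": 0},
  {"name": "carboxylic acid", "smarts": "[CX3](=O)[OX2H1]",
   "site": 3, "mean_pka": 3.5, "pka_sd": 1.0, "prot_charge": 0, "deprot_charge": -1},
  {"name": "carboxylate (input anion)", "smarts": "[CX3](=O)[OX1-]",
   "site": 3, "mean_pka": 3.5, "pka_sd": 1.0, "prot_charge": 0, "deprot_charge": -1},
  {"name": "tetrazole NH", "smarts": "[nX3H1]1nnnc1",
   "site": 1, "mean_pka": 4.9, "pka_sd": 1.0, "prot_charge": 0, "deprot_charge": -1},
  {"name": "sulfonamide NH", "smarts": "[SX4](=O)(=O)[NX3;H1]",
   "site": 4, "mean_pka": 10.1, "pka_sd": 1.0, "prot_charge": 0, "deprot_charge": -1},
  {"name": "phosphate/phosphonate OH", "smarts": "[PX4](=O)[OX2H1]",
   "site": 3, "mean_pka": 2.1, "pka_sd": 1.0, "prot_charge": 0, "deprot_charge": -1},
  {"name": "phenol", "smarts": "c[OX2H1]",
   "site": 2, "mean_pka": 9.9, "pka_sd": 1.0, "prot_charge": 0, "deprot_charge": -1},
  {"name": "thiophenol", "smarts": "c[SX2H1]",
   "site": 2, "mean_pka": 6.6, "pka_sd": 1.0, "prot_charge": 0, "deprot_charge": -1},
  {"name": "thiol", "smarts": "[CX4][SX2H1]",
   "site": 2, "mean_pka": 9.1, "pka_sd": 1.0, "prot_charge": 0, "deprot_charge": -1},
  {"name": "guanidine", "smarts": "[NX3][CX3](=[NX2;H1,H0])[NX3]",
   "site": 3, "mean_pka": 12.5, "pka_sd": 1.0, "prot_charge": 1, "deprot_charge": 0},
  {"name": "amidine", "smarts": "[CX3](=[NX2;H1,H0])[NX3;H2]",
   "site": 2, "mean_pka": 11.5, "pka_sd": 1.0, "prot_charge": 1, "deprot_charge": 0},
  {"name": "imidazole basic N", "smarts": "[nX2]1c[nX3H1]cc1",
   "site": 1, "mean_pka": 7.0, "pka_sd": 1.0, "prot_charge": 1, "deprot_charge": 0},
  {"name": "aromatic N (pyridine-type)", "smarts": "[nX2;+0]",
   "site": 1, "mean_pka": 5.2, "pka_sd": 1.0, "prot_charge": 1, "deprot_charge": 0},
  {"name": "aniline NH2", "smarts": "[NX3;H2;+0]c",
   "site": 1, "mean_pka": 4.6, "pka_sd": 1.0, "prot_charge": 1, "deprot_charge": 0},
  {"name": "primary aliphatic amine", "smarts": "[NX3;H2;+0][CX4]",
   "site": 1, "mean_pka": 10.3, "pka_sd": 1.0, "prot_charge": 1, "deprot_charge": 0},
  {"name": "ammonium (input cation)", "smarts": "[NX4;H3;+1][CX4]",
   "site": 1, "mean_pka": 10.3, "pka_sd": 1.0, "prot_charge": 1, "deprot_charge": 0},
  {"name": "secondary aliphatic amine", "smarts": "[NX3;H1;+0]([CX4])[CX4]",
   "site": 1, "mean_pka": 10.7, "pka_sd": 1.0, "prot_charge": 1, "deprot_charge": 0},
  {"name": "tertiary aliphatic amine", "smarts": "[NX3;H0;+0]([CX4])([CX4])[CX4]",
   "site": 1, "mean_pka": 9.8, "pka_sd": 1.0, "prot_charge": 1, "deprot_charge": 0},
  {"name": "aromatic NH (pyrrole-type)", "smarts": "[nX3H1]",
   "site": 1, "mean_pka": 16.5, "pka_sd": 1.0, "prot_charge": 0, "deprot_charge": -1},
  {"name": "aliphatic alcohol", "smarts": "[CX4][OX2H1]",
   "site": 2, "mean_pka": 14.8, "pka_sd": 1.0, "prot_charge": 0, "deprot_charge": -1}
]
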