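{
  "species": [
    {"name": "LYZ",  "tm": 67.8, "dh": 800, "a330": 1.0, "a350": 1.0,
     "d330": -0.01, "d350": 0.01, "slope330": 0.0, "slope350": 0.0},
    {"name": "LCN1", "tm": 69.4, "dh": 800, "a330": 1.0, "a350": 1.0,
     "d330": -0.01, "d350": 0.01, "slope330": 0.0, "slope350": 0.0},
    {"name": "IGA",  "tm": 72.9, "dh": 800, "a330": 1.0, "a350": 1.0,
     "d330": -0.01, "d350": 0.01, "slope330": 0.0, "slope350": 0.0},
    {"name": "HSA",  "tm": 75.1, "dh": 800, "a330": 1.0, "a350": 1.0,
     "d330": -0.01, "d350": 0.01, "slope330": 0.0, "slope350": 0.0},
    {"name": "LTF",  "tm": 67.4, "dh": 800, "a330": 1.0, "a350": 1.0,
     "d330": -0.01, "d350": 0.01, "slope330": 0.0, "slope350": 0.0}
  ],
  "ligands": [
    {"ligand": "MYRISTATE", "shifts": {"HSA": {"tm": 80.3}, "LYZ": {"tm": 55.6}}},
    {"ligand": "FE3", "shifts": {"LTF": {"tm": 95.0}}},
    {"ligand": "LATANOPROST", "shifts": {}}
  ],
  "presets": {
    "CONTROL": {"HSA": 140, "LTF": 110, "LYZ": 50, "IGA": 30, "LCN1": 100},
    "POAG":    {"HSA": 110, "LTF": 150, "LYZ": 30, "IGA": 30, "LCN1": 60}
  }
}
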