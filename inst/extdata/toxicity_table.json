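{
  "version": "1.0",
  "comment": "Per-element toxicity constants (USEPA RSL residential). RfDo: oral reference dose mg/kg-day; RfC: inhalation reference concentration mg/m3; ABSd: dermal absorption fraction; GIABS: gastrointestinal absorption fraction; RBA: relative bioavailability; CSFo: oral slope factor (mg/kg-day)^-1; IUR: inhalation unit risk (ug/m3)^-1. CSFo/IUR present only for the carcinogens assessed (Cr, Cd, Ni, Co). Cr is assessed as hexavalent chromium -- a speciation assumption; total-Cr users should override CSFo/IUR/GIABS.",
  "elements": {
    "Al": { "RfDo": 1.0,    "RfC": 5e-3, "ABSd": 0.001, "GIABS": 1,     "RBA": 1 },
    "Cd": { "RfDo": 1e-3,   "RfC": 1e-5, "ABSd": 0.001, "GIABS": 0.025, "RBA": 1, "IUR": 1.8e-3 },
    "Co": { "RfDo": 3e-4,   "RfC": 6e-6, "ABSd": 0.001, "GIABS": 1,     "RBA": 1, "IUR": 9e-3 },
    "Cr": { "RfDo": 3e-3,   "RfC": 1e-4, "ABSd": 0.001, "GIABS": 0.025, "RBA": 1, "CSFo": 0.5, "IUR": 8.4e-2 },
    "Cu": { "RfDo": 4e-2,                "ABSd": 0.001, "GIABS": 1,     "RBA": 1 },
    "Fe": { "RfDo": 0.7,                 "ABSd": 0.001, "GIABS": 1,     "RBA": 1 },
    "Mn": { "RfDo": 2.4e-2, "RfC": 5e-5, "ABSd": 0.001, "GIABS": 0.04,  "RBA": 1 },
    "Ni": { "RfDo": 2e-2,   "RfC": 9e-5, "ABSd": 0.001, "GIABS": 0.04,  "RBA": 1, "IUR": 2.6e-4 },
    "Pb": { "RfDo": 3.5e-3,              "ABSd": 0.001, "GIABS": 1,     "RBA": 1 },
    "Zn": { "RfDo": 0.3,                 "ABSd": 0.001, "GIABS": 1,     "RBA": 1 }
  }
}
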