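{
  "version": "1.0",
  "comment": "USEPA residential soil exposure defaults (RSL). IRS: soil ingestion rate mg/day; EFr: exposure frequency days/year; ED: exposure duration years; BW: body weight kg; SA: exposed skin surface cm2/day; AF: soil adherence factor mg/cm2. PEF: particulate emission factor m3/kg. Non-carcinogenic averaging time is ED*365 days per receptor; carcinogenic averaging time is AT_carcinogenic_years*365 days.",
  "child": { "IRS": 200, "EFr": 350, "ED": 6,  "BW": 15, "SA": 2373, "AF": 0.2 },
  "adult": { "IRS": 100, "EFr": 350, "ED": 20, "BW": 80, "SA": 6032, "AF": 0.07 },
  "PEF": 1.36e9,
  "AT_carcinogenic_years": 70
}
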