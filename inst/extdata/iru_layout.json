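{
  "name": "iru",
  "comment": "Assembly-line configuration for the irumamycin-like fixture. Hemiketal ring carbons are provisional (not printed); lactone closure at the C19 hydroxyl gives the 20-membered macrolactone.",
  "modules": {
    "8": { "ks_gatekeeper_override": "malonyl" },
    "11": { "iterative": true, "olefin_shift": true },
    "12": { "at_borrowed_from": 11 }
  },
  "ring_closure": {
    "lactone_oxygen_carbon": 19,
    "hemiketal": { "ketone_carbon": 3, "hydroxyl_carbon": 7, "provisional": true }
  },
  "tailoring": [
    { "kind": "dehydration", "site": [23] },
    { "kind": "epoxidation", "site": [23, 24] },
    { "kind": "glycosylation", "site": [25],
      "delta": { "C": 7, "H": 11, "N": 1, "O": 5 },
      "comment": "carbamoylated deoxyhexose residue, net of condensation water; validated against the adduct back-calculation" }
  ],
  "labeling": { "exchangeable_slots": 1, "enrichment": 0.5 },
  "olefin_shift_path": 1
}
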