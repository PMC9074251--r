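{
  "components": ["water", "solute", "ester"],
  "molar_mass": [18.015, 88.106, 172.26],
  "T_ref_K": 298.15,
  "pairs": [
    {
      "i": "water",
      "j": "solute",
      "tau_ij": 0.816328311599791,
      "tau_ji": 1.49040929247276,
      "alpha": 0.2
    },
    {
      "i": "water",
      "j": "ester",
      "tau_ij": 4.08893505372107,
      "tau_ji": 3.01092800450278,
      "alpha": 0.2
    },
    {
      "i": "solute",
      "j": "ester",
      "tau_ij": -0.302411966887303,
      "tau_ji": -0.203983896849677,
      "alpha": 0.2
    }
  ]
}
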