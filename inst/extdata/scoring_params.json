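{
  "lj": {
    "element": ["C", "N", "O", "S"],
    "sigma": [3.4, 3.25, 3.0, 3.6],
    "eps": [0.15, 0.16, 0.2, 0.2]
  },
  "coulomb_k": 332.06,
  "kT": 0.593,
  "dielectric": "r4",
  "eps_const": 80.0,
  "hbond": {"eps": 2.0, "r0": 2.9, "rcut": 4.5},
  "torsion_k": 0.5,
  "restraint_k": 100.0,
  "cutoff": 8.0
}
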