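# Measurement-buffer ionic compositions (explicit speciation; conc in mol/L).
# 0.1x phosphate solution: 240 uM NaH2PO4 + 760 uM Na2HPO4.
phosphate_solution_0.1x:
  - species: "Na+"
    conc: 1.76e-3
    charge: 1
  - species: "H2PO4-"
    conc: 0.24e-3
    charge: -1
  - species: "HPO4(2-)"
    conc: 0.76e-3
    charge: -2
# 1x PBS: 138 mM NaCl, 2.7 mM KCl, 8 mM Na2HPO4, 1.5 mM KH2PO4.
pbs_1x:
  - species: "Na+"
    conc: 154e-3
    charge: 1
  - species: "K+"
    conc: 4.2e-3
    charge: 1
  - species: "Cl-"
    conc: 140.7e-3
    charge: -1
  - species: "HPO4(2-)"
    conc: 8e-3
    charge: -2
  - species: "H2PO4-"
    conc: 1.5e-3
    charge: -1
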