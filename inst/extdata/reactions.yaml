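# Catabolic sulfate-reduction reactions, written per mole of sulfate
# (8 electrons transferred), bicarbonate as the carbon product, liquid
# water as solvent. Coefficients: negative = reactant, positive = product.
- id: co_sulfate
  donor: CO
  acceptor: SO4-2
  n_electrons: 8
  stoichiometry:
    CO: -4
    SO4-2: -1
    H2O: -4
    HCO3-: 4
    HS-: 1
    H+: 3
- id: h2_sulfate
  donor: H2
  acceptor: SO4-2
  n_electrons: 8
  stoichiometry:
    H2: -4
    SO4-2: -1
    H+: -1
    HS-: 1
    H2O: 4
- id: ch4_sulfate
  donor: CH4
  acceptor: SO4-2
  n_electrons: 8
  stoichiometry:
    CH4: -1
    SO4-2: -1
    HCO3-: 1
    HS-: 1
    H2O: 1
- id: acetate_sulfate
  donor: acetate
  acceptor: SO4-2
  n_electrons: 8
  stoichiometry:
    acetate: -1
    SO4-2: -1
    HCO3-: 2
    HS-: 1
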