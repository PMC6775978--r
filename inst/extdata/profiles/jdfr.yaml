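# In situ conditions for Juan de Fuca Ridge flank crustal fluids.
# temperature and sulfate are field-constrained (64 degC; ~18 mM sulfate);
# the remaining analytes and pH/ionic strength are documented placeholder
# values typical of anoxic marine crustal fluids and are fully overridable.
name: jdfr
temperature_K: 337.15
pH: 7.5
ionic_strength_mol_kg: 0.7
activity_model: ideal
concentrations_mol_kg:
  SO4-2: 0.018     # field-constrained (~18 mM)
  HS-: 1.0e-05     # placeholder
  HCO3-: 2.0e-03   # placeholder (seawater-like DIC)
  H2: 1.0e-06      # placeholder
  CH4: 1.0e-06     # placeholder
  CO: 1.0e-06      # placeholder (sweep variable)
  acetate: 1.0e-06 # placeholder (sweep variable)
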