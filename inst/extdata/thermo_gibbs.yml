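# Standard Gibbs free energies of formation at 25 C (kJ/mol), compiled
# from the Thauer/Stumm-Morgan lineage of tabulations commonly used for
# microbial bioenergetics. phase: aq = aqueous (activity = molar
# concentration), s = solid (unit activity), l = liquid water (unit
# activity). Edit and pass to thermo_table(path=...) to use other
# constants.
species:
  acetate:     {dg0f: -369.4, phase: aq, provenance: Thauer-1977}
  lactate:     {dg0f: -517.8, phase: aq, provenance: Thauer-1977}
  bicarbonate: {dg0f: -586.9, phase: aq, provenance: Thauer-1977}
  "Fe2+":      {dg0f: -78.9,  phase: aq, provenance: CODATA}
  goethite:    {dg0f: -488.6, phase: s,  provenance: Stumm-Morgan}
  "H+":        {dg0f: 0.0,    phase: aq, provenance: convention}
  H2O:         {dg0f: -237.2, phase: l,  provenance: CODATA}
  sulfate:     {dg0f: -744.6, phase: aq, provenance: Thauer-1977}
  "HS-":       {dg0f: 12.1,   phase: aq, provenance: Thauer-1977}
  H2S:         {dg0f: -27.9,  phase: aq, provenance: Thauer-1977}
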