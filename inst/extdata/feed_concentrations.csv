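solute,C_mol_L
Ur,1.67e-2
Crn,8.85e-4
Ptot,2.9e-3
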