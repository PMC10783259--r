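category,share_value,basis,plasticity,partial_fraction_override,note
Surface treatments,2160,MASS,PARTIAL,,Metric tons; textiles carpet apparel upholstery
Paper protection,1490,MASS,NONE,,Food and nonfood paper applications
Firefighting foams,151,MASS,NONE,,
Other performance chemicals,680,MASS,PARTIAL,,Floor polishes coating additives surfactants cleaners
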