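category,share_value,basis,plasticity,partial_fraction_override,note
APFO used in fluoropolymer manufacture,57,EMISSIONS_PERCENT,FULL,,Percent of total PFCA-related emissions
APFO manufacture,10,EMISSIONS_PERCENT,PARTIAL,,Percent of total PFCA-related emissions
APFO for fluoropolymer dispersions,5,EMISSIONS_PERCENT,FULL,,Percent of total PFCA-related emissions
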