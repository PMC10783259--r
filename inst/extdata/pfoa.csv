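category,share_value,basis,plasticity,partial_fraction_override,note
APFO used in fluoropolymer manufacture,79.2,EMISSIONS_PERCENT,FULL,,All plastics related
APFO manufacture,13.8,EMISSIONS_PERCENT,PARTIAL,,Includes nonplastic emissions such as AFFF
APFO for fluoropolymer dispersions,6.9,EMISSIONS_PERCENT,FULL,,All plastic related
Rounding residual,0.1,EMISSIONS_PERCENT,NONE,,Synthetic residual row: printed rescaled column sums to 99.9
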