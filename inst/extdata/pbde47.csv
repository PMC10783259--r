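category,share_value,basis,plasticity,partial_fraction_override,note
Manufacture of FPUF,96.5,PERCENT,FULL,,Midpoint of the reported 95-98% range; furniture industry
"Commercial adhesive products, other uses",3.5,PERCENT,PARTIAL,,
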