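category,share_value,basis,plasticity,partial_fraction_override,note
Polymer formulation and processing,5900,MASS,FULL,,Tons per year; flooring garden hoses automotive fiberglass
Paints (nitrocellulose lacquers),160,MASS,FULL,,Nitrocellulose lacquers are polymeric
Adhesives,1890,MASS,PARTIAL,,Paper and packaging construction automotive
Grouting agents,80,MASS,PARTIAL,,Construction work
"Other, nonpolymeric",250,MASS,NONE,,Solvent for oil-soluble dyes insecticides peroxides
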