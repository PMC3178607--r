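# Atomic solvation parameters sigma (kJ mol-1 A-2) per atom class,
# Eisenberg-McLachlan-style: apolar burial favourable, polar burial costly.
atom_class	sigma
lipophilic	0.0670
polar_neutral	0.0000
donor	-0.0251
acceptor	-0.0251
donor_acceptor	-0.0251
hydrogen	0.0000
other	0.0000
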