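# Experimental binding free energies (kJ/mol) for the five HLA-A*0201
# (Madden) crystal complexes; original-publication predictions included
# for comparison columns.
peptide	pdb_id	dg_exp	dg_rognan	dg_paper
TLTSCNTSV	1HHG	-37.32	-36.85	-37.19
FLPSDFFPSV	1HHH	-48.45	-48.56	-48.41
GILGFVFTL	1HHI	-46.94	-47.03	-47.01
ILKEPVHGV	1HHJ	-37.60	-38.96	-37.74
LLFGYPVYV	1HHK	-45.48	-45.57	-45.43
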