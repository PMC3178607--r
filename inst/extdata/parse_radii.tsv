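# PARSE-style van der Waals radii (Angstrom), per element
element	radius
H	1.00
C	1.70
N	1.50
O	1.40
S	1.85
P	1.90
X	1.70
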