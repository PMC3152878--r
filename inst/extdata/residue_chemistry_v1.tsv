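# coilDock residue chemistry table, version 1
# polarity: charged / polar / nonpolar (His counted charged, Gly polar; see vignette)
# max_sasa: theoretical maximum accessible surface area of residue X in Gly-X-Gly (A^2)
resname	one_letter	polarity	max_sasa
ALA	A	nonpolar	129
ARG	R	charged	274
ASN	N	polar	195
ASP	D	charged	193
CYS	C	polar	167
GLN	Q	polar	225
GLU	E	charged	223
GLY	G	polar	104
HIS	H	charged	224
ILE	I	nonpolar	197
LEU	L	nonpolar	201
LYS	K	charged	236
MET	M	nonpolar	224
PHE	F	nonpolar	240
PRO	P	nonpolar	159
SER	S	polar	155
THR	T	polar	172
TRP	W	polar	285
TYR	Y	polar	263
VAL	V	nonpolar	174
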