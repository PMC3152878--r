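# coilDock side-chain formal charge assignment, version 1
# His treated as positively charged (both ring nitrogens); see vignette
resname	atom	sign
ASP	OD1	-
ASP	OD2	-
GLU	OE1	-
GLU	OE2	-
LYS	NZ	+
ARG	NH1	+
ARG	NH2	+
ARG	NE	+
HIS	ND1	+
HIS	NE2	+
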