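# Reference row: mean stable transient heteromultimer interface, version 1
field	value_lo	value_hi
interface_asa_percent	11.2	11.2
pct_polar	32.2	32.2
pct_nonpolar	39.5	39.5
pct_charged	28.2	28.2
hbonds_per_100A2	1	1
saltbridges_per_100A2	2	6
surface_pct_polar	31.90	31.90
surface_pct_nonpolar	38.00	38.00
surface_pct_charged	30.00	30.00
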