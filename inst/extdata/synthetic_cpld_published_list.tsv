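gene	hgvsp
JAK2	V617F
DNMT3A	R882H
DNMT3A	R882C
DNMT3A	R736H
TET2	H1904R
TET2	I1873T
TET2	T1884A
SF3B1	K700E
SF3B1	K666N
SRSF2	P95H
SRSF2	P95L
IDH1	R132H
IDH2	R140Q
GNB1	K57E
MYD88	L252P
MPL	W515L
CBL	Y371H
PPM1D	R552X
ASXL1	G646Wfs
CALR	L367Tfs
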