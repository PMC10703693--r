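gene
DNMT3A
TET2
ASXL1
JAK2
SF3B1
SRSF2
TP53
PPM1D
GNB1
GNAS
IDH1
IDH2
CBL
KRAS
NRAS
BRAF
CALR
MPL
RUNX1
STAG2
BCOR
BCORL1
EZH2
KIT
NF1
PHF6
RAD21
SETBP1
SMC1A
SMC3
WT1
ZRSR2
CSF3R
CUX1
ETV6
FLT3
GATA2
JAK1
JAK3
KDM6A
LUC7L2
MYD88
NPM1
PDS5B
PIK3CA
PRPF8
PTPN11
SH2B3
STAT3
CTCF
CEBPA
DDX41
CHEK2
MTA2
PRR14L
SUZ12
EED
ATM
CREBBP
EP300
KMT2D
ARID1A
ARID2
ASXL2
DNMT3B
TET3
SMC4
NRIP1
ELF1
RTEL1
TERT
GNB2
CSNK1A1
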