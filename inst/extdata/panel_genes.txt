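ABL1
AKT1
AKT2
ALK
APC
AR
ARID1A
ATM
ATR
ATRX
AURKA
AURKB
AXL
BAP1
BCL2
BCL6
BRAF
BRCA1
BRCA2
CCND1
CCNE1
CDH1
CDK4
CDK6
CDKN2A
CEBPA
CHEK1
CHEK2
CREBBP
CSF1R
CTNNB1
DDR2
DICER1
DNMT3A
EGFR
EP300
EPHA3
EPHB1
ERBB2
ERBB3
ERBB4
ERCC2
ESR1
EZH2
FANCA
FANCC
FANCD2
FANCE
FANCF
FANCG
FBXW7
FGFR1
FGFR2
FGFR3
FGFR4
FLT1
FLT3
FLT4
FOXL2
GATA1
GATA2
GATA3
GNA11
GNAQ
GNAS
HNF1A
HRAS
IDH1
IDH2
IGF1R
IKZF1
IL6ST
IL7R
JAK1
JAK2
JAK3
KDM6A
KDR
KEAP1
KIT
KMT2A
KRAS
LOC100507346
MAP2K1
MAP2K2
MAP2K4
MAP3K1
MCL1
MDM2
MDM4
MET
MLH1
MLL2
MPL
MRE11
MSH2
MSH6
MTOR
MYC
MYCL
MYCN
NBN
NF1
NF2
NFE2L2
NKX2-1
NOTCH1
NOTCH2
NPM1
NRAS
NTRK1
NTRK2
NTRK3
PA2G4
PALB2
PAX5
PBRM1
PDGFRA
PDGFRB
PIK3CA
PIK3CB
PIK3R1
PMS2
PTCH1
PTEN
PTPN11
RAD50
RAD51
RAF1
RB1
RET
RICTOR
ROS1
RUNX1
SDHA
SDHB
SETD2
SF3B1
SMAD2
SMAD4
SMARCA4
SMARCB1
SMO
SOX2
SRC
STAT3
STK11
SUFU
TERT
TET2
TGFBR2
TOP1
TP53
TSC1
TSC2
TSHR
U2AF1
VHL
WT1
XPO1
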