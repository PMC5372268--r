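symbol
TNMD
TSPAN9
PRICKLE3
RAD51
MCM10
TCF3
ATP2A3
OPHN1
FBXL19
PCK2
PLTP
E2F1
PCYT1B
CKM
APBA1
CNTNAP1
FOXM1
KIF20A
CIT
HJURP
E2F8
KLF16
APOC1
ATP8B3
EPHB2
CTIF
TICRR
CTU1
CPXCR1
GRIK4
C16orf78
CKB
VKORC1
TK1
METTL7B
MZB1
ZNF296
RRM2
JUP
PCP2
CADM2
SLC25A22
KLHL28
GJC1
MARCH11
GAS2L1
MITF
HIST1H2BM
SLC25A29
SRC
MYO1C
RNU12-2P
Y_RNA
D86998.1
IGLV6-57
IGLV3-21
IGHG1
IGHJ1
IGHV6-1
IGHV4-28
AP005482.3
RP3-407E4.4
RP11-535M15.1
IPPKP1
FAM195B
RP11-69C17.2
HDGFP1
SCAMP4
RD3L
TUBB4AP1
SDAD1P2
RP11-321L2.1
SPATA31B1P
AC005772.2
RP11-22C8.1
VN1R38P
ITGA9-AS1
NIFK-AS1
B3GNT9
RP11-252M21.6
RN7SL60P
RP11-266N13.2
RP11-517I3.1
RP11-364C11.2
RACGAP1P
RP11-545N8.3
RP11-81A1.3
RP11-2C24.5
AF213884.2
PRKCA-AS1
CTD-2319I12.2
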