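IL1A
IL1B
IL6
IL8
TNF
PTGS1
PTGS2
FOS
FOSB
FOSL1
FOSL2
JUN
JUNB
JUND
NFKB1
NFKB2
REL
RELA
RELB
GBP1
IFI16
IFI27
IFI27L1
IFI27L2
IFI30
IFI35
IFI44
IFI44L
IFI6
IFIH1
IFIT1
IFIT1L
IFIT2
IFIT3
IFIT5
IFITM1
IFITM2
IFITM3
IFITM4P
IFITM5
IFNB1
IRF2
IRF7
IRF8
MX1
MX2
OAS1
OAS2
OAS3
OASL
JCHAIN
IGLL1
IGLL3
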