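ALS2
ANG
ATXN2
C9ORF72
CHCHD10
CHMP2B
DCTN1
ERBB4
FIG4
FUS
HNRNPA1
MATR3
NEFH
OPTN
PFN1
PRPH
SETX
SIGMAR1
SOD1
SPG11
SQSTM1
TARDBP
TBK1
TUBA4A
UBQLN2
VAPB
VCP
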