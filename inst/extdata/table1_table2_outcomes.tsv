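# Binary lipid-vesicle pulldown outcomes for 67 full-length human PH
# domain-containing proteins assayed by single-molecule pulldown against
# vesicles carrying each of the seven phosphoinositide species plus
# phosphatidic acid (PA) and a lipid-free control.
# outcome: BINDS = bound >= 1 PIP-containing vesicle with specificity;
#          DOES_NOT_BIND = bound none; PROMISCUOUS = bound vesicles
#          nonspecifically (including PA and/or the control), interpreted
#          as likely misfolding and excluded from binder/non-binder calls.
# pips_bound: semicolon-separated vesicle types pulled down (ALL for
#          promiscuous all-vesicle binders).
id	outcome	pips_bound
BTK	BINDS	PI(3,4,5)P3
ITK	BINDS	PI(3,4,5)P3
SKAP1	BINDS	PI(3,4,5)P3
PLCD4	BINDS	PI(3,4,5)P3
SKAP2	BINDS	PI(3,4,5)P3
EXOC8	BINDS	PI(4,5)P2
PSD2	BINDS	PI(4,5)P2
ARHGAP12	BINDS	PI(4,5)P2
DEF6	BINDS	PI(3,4)P2
PLEKHA1	BINDS	PI(3,4)P2
AFAP1L1	BINDS	PI(3,5)P2
ARHGEF7	BINDS	PI(3,5)P2
ARHGEF16	BINDS	PI(3)P
DOK2	BINDS	PI(3)P
PLEKHB2	BINDS	PI(3)P
PLEKHF1	BINDS	PI(3)P
SWAP70	BINDS	PI(3)P
CNKSR1	BINDS	PI(4)P
GAB1	BINDS	PI(4)P
ARHGEF9	BINDS	PI(5)P
NGEF	BINDS	PI(5)P
SBF2	BINDS	PI(3,4,5)P3;PI(4,5)P2
ARHGEF39	BINDS	PI(3,4,5)P3;PI(3,4)P2
FERMT3	BINDS	PI(3,4,5)P3;PI(3,4)P2
GAB2	BINDS	PI(3,4,5)P3;PI(3,4)P2
ARHGEF5	BINDS	PI(4,5)P2;PI(3,4)P2
ARHGEF3	BINDS	PI(4,5)P2;PI(3,5)P2
ARHGAP26	BINDS	PI(3,4)P2;PI(3)P
ACAP1	BINDS	PI(3,4)P2;PI(3,5)P2;PI(4)P
OSBPL10	BINDS	PI(3,4)P2;PI(3,5)P2;PI(4)P
ADAP1	BINDS	PI(3,4,5)P3;PI(4,5)P2;PI(3,4)P2
MCF2L2	BINDS	PI(3,4,5)P3;PI(4,5)P2;PI(3,4)P2;PI(3,5)P2;PI(5)P
OSBPL5	BINDS	PI(4,5)P2;PI(3,4)P2;PI(3,5)P2;PI(4)P;PI(5)P
PLEKHJ1	BINDS	PI(3,4,5)P3;PI(4,5)P2;PI(3,4)P2;PI(3,5)P2;PI(5)P
VAV1	BINDS	PI(3,4,5)P3;PI(4,5)P2;PI(3,4)P2;PI(3,5)P2;PI(5)P
ARHGAP15	BINDS	PI(3,4,5)P3;PI(4,5)P2;PI(3,4)P2;PI(3,5)P2;PI(3)P;PI(4)P
PLEKHO1	PROMISCUOUS	PI(3,4,5)P3;PI(4,5)P2;PI(3,4)P2;PI(3)P;PI(5)P;PA
CERT1	PROMISCUOUS	ALL
NET1	PROMISCUOUS	ALL
SPATA13	PROMISCUOUS	ALL
AFAP1	DOES_NOT_BIND
APPL1	DOES_NOT_BIND
APPL2	DOES_NOT_BIND
ARHGAP25	DOES_NOT_BIND
BMX	DOES_NOT_BIND
DOK1	DOES_NOT_BIND
DOK3	DOES_NOT_BIND
DOK4	DOES_NOT_BIND
FERMT2	DOES_NOT_BIND
FGD5	DOES_NOT_BIND
GRB7	DOES_NOT_BIND
GRB14	DOES_NOT_BIND
GRK2	DOES_NOT_BIND
KIF1B	DOES_NOT_BIND
OSBPL8	DOES_NOT_BIND
PHETA2	DOES_NOT_BIND
PLCG2	DOES_NOT_BIND
PLEK	DOES_NOT_BIND
PLEKHF2	DOES_NOT_BIND
PLEKHN1	DOES_NOT_BIND
PLEKHO2	DOES_NOT_BIND
PRKD3	DOES_NOT_BIND
PSD4	DOES_NOT_BIND
RASA1	DOES_NOT_BIND
RASGRF1	DOES_NOT_BIND
SOS2	DOES_NOT_BIND
STAP1	DOES_NOT_BIND
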