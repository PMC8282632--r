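# Training labels for the 67 PH-domain sequences behind the RFC matrix:
# 35 binder and 32 non-binder domains.  The binder side is the 36
# specifically PIP-binding proteins minus the two dual-PH-domain proteins
# (ADAP1, AFAP1L1, dropped because the responsible domain is unknown)
# plus the AKT1 PH domain as a positive control.  The non-binder side is
# the 27 proteins that bound no PIP; the 5 additional non-binder PH
# domains (second domains of multi-PH proteins) are not identifiable from
# the published tables, so they carry placeholder ids here -- hence the
# _synthetic filename.  Group counts, not identities, are the ground
# truth this fixture encodes.
id	label
AKT1	binder
BTK	binder
ITK	binder
SKAP1	binder
PLCD4	binder
SKAP2	binder
EXOC8	binder
PSD2	binder
ARHGAP12	binder
DEF6	binder
PLEKHA1	binder
ARHGEF7	binder
ARHGEF16	binder
DOK2	binder
PLEKHB2	binder
PLEKHF1	binder
SWAP70	binder
CNKSR1	binder
GAB1	binder
ARHGEF9	binder
NGEF	binder
SBF2	binder
ARHGEF39	binder
FERMT3	binder
GAB2	binder
ARHGEF5	binder
ARHGEF3	binder
ARHGAP26	binder
ACAP1	binder
OSBPL10	binder
MCF2L2	binder
OSBPL5	binder
PLEKHJ1	binder
VAV1	binder
ARHGAP15	binder
AFAP1	nonbinder
APPL1	nonbinder
APPL2	nonbinder
ARHGAP25	nonbinder
BMX	nonbinder
DOK1	nonbinder
DOK3	nonbinder
DOK4	nonbinder
FERMT2	nonbinder
FGD5	nonbinder
GRB7	nonbinder
GRB14	nonbinder
GRK2	nonbinder
KIF1B	nonbinder
OSBPL8	nonbinder
PHETA2	nonbinder
PLCG2	nonbinder
PLEK	nonbinder
PLEKHF2	nonbinder
PLEKHN1	nonbinder
PLEKHO2	nonbinder
PRKD3	nonbinder
PSD4	nonbinder
RASA1	nonbinder
RASGRF1	nonbinder
SOS2	nonbinder
STAP1	nonbinder
second_ph_domain_1	nonbinder
second_ph_domain_2	nonbinder
second_ph_domain_3	nonbinder
second_ph_domain_4	nonbinder
second_ph_domain_5	nonbinder
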