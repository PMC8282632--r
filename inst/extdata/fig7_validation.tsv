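# Prospective validation of the RFC binding predictions: 20 predicted
# binders and 11 predicted non-binders were assayed by single-molecule
# pulldown.  19/20 predicted binders bound at least one PIP vesicle; PSD3
# (the single false positive) bound none of the seven.  8/11 predicted
# non-binders bound nothing; 3 bound at least one PIP, among them CYTH3,
# whose atypical nine-stranded PH fold may defeat the alignment-based
# score.
# Only PSD3 and CYTH3 are identified by name here; the remaining ids are
# placeholders (the published counts, not the identities, are what this
# fixture carries).
id	predicted	outcome
pred_binder_01	binder	BINDS
pred_binder_02	binder	BINDS
pred_binder_03	binder	BINDS
pred_binder_04	binder	BINDS
pred_binder_05	binder	BINDS
pred_binder_06	binder	BINDS
pred_binder_07	binder	BINDS
pred_binder_08	binder	BINDS
pred_binder_09	binder	BINDS
pred_binder_10	binder	BINDS
pred_binder_11	binder	BINDS
pred_binder_12	binder	BINDS
pred_binder_13	binder	BINDS
pred_binder_14	binder	BINDS
pred_binder_15	binder	BINDS
pred_binder_16	binder	BINDS
pred_binder_17	binder	BINDS
pred_binder_18	binder	BINDS
pred_binder_19	binder	BINDS
PSD3	binder	DOES_NOT_BIND
CYTH3	nonbinder	BINDS
pred_nonbinder_02	nonbinder	BINDS
pred_nonbinder_03	nonbinder	BINDS
pred_nonbinder_04	nonbinder	DOES_NOT_BIND
pred_nonbinder_05	nonbinder	DOES_NOT_BIND
pred_nonbinder_06	nonbinder	DOES_NOT_BIND
pred_nonbinder_07	nonbinder	DOES_NOT_BIND
pred_nonbinder_08	nonbinder	DOES_NOT_BIND
pred_nonbinder_09	nonbinder	DOES_NOT_BIND
pred_nonbinder_10	nonbinder	DOES_NOT_BIND
pred_nonbinder_11	nonbinder	DOES_NOT_BIND
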