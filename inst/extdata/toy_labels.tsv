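# Toy labels for toy_alignment.fasta
id	label
dom1	binder
dom2	binder
dom3	binder
dom4	nonbinder
dom5	nonbinder
dom6	nonbinder
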