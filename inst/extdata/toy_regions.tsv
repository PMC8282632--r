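# Toy loop regions for toy_alignment.fasta (1-based closed intervals)
name	start	end
b1b2	1	4
b3b4	5	7
b6b7	8	9
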