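>dom1
KRWAC-DEFGHI
>dom2
KKWAC-DEFGHL
>dom3
RRWGCTDE-GHI
>dom4
QEWAC-NEFGHI
>dom5
QDWGCTNE-GHL
>dom6
EEWACTNEFGHI
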