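karyotype	count
2n=8 normal	7
2n=9 trisomy MLI1	28
2n=10 tetrasomy MLI1	14
2n=9 extra B chromosome	1
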