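c1	10000000
c2	10000000
c3	10000000
c4	10000000
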