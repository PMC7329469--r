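FAM1	child	father	mother	1	2
FAM1	father	0	0	1	1
FAM1	mother	0	0	2	1
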