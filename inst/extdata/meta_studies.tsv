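label	beta	se	ci_low	ci_high	p	n
ukbiobank	-0.025	0.006	NA	NA	3e-5	119688
giant	-0.019	NA	-0.031	-0.008	0.003	105643
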