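contrast	or	ci_low	ci_high
additive	1.15	1.10	1.21
het_vs_hom_ref	1.06	0.99	1.14
hom_alt_vs_hom_ref	1.48	1.32	1.65
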