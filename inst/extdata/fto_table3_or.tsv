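trait	contrast	or	ci_low	ci_high
obese	het_vs_hom_ref	1.15	1.12	1.19
obese	hom_alt_vs_hom_ref	1.48	1.41	1.55
severely_obese	het_vs_hom_ref	1.28	1.16	1.41
severely_obese	hom_alt_vs_hom_ref	2.12	1.88	2.38
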