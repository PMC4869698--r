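class	n	mean	sd
hom_ref	42835	27.27	4.68
het	57524	27.54	4.80
hom_alt	19329	28.07	5.11
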