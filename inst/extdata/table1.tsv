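method	level	success_pct	n_individuals	n_success	n_success_reconstructed
morphological	family	100.0	22	22	TRUE
morphological	genus	59.1	22	13	TRUE
morphological	species	54.5	22	12	TRUE
standard_barcoding	family	100.0	22	22	TRUE
standard_barcoding	genus	86.4	22	19	TRUE
standard_barcoding	species	63.6	22	14	TRUE
metabarcoding	family	95.5	22	21	TRUE
metabarcoding	genus	81.8	22	18	TRUE
metabarcoding	species	54.5	22	12	TRUE
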