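name	c	h	o	n	s	role
ethanol	1	3	0.5	0	0	substrate
paa	1	1	0.25	0	0	substrate
biomass	1	1.8	0.5	0.2	0	biomass
peng	1	1.125	0.25	0.125	0.0625	product
ohpaa	1	1	0.375	0	0	byproduct
toc_byproduct	1	1.8	0.5	0.2	0	byproduct
co2	1	0	2	0	0	gas
o2	0	0	2	0	0	gas
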