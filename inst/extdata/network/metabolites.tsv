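id	c	h	o	n	s	balanced	exempt
ethanol	2	6	1	0	0	1	0
acald	2	4	1	0	0	1	0
ac	2	4	2	0	0	1	0
accoa	2	4	2	0	0	1	0
pyr	3	4	3	0	0	1	0
oaa	4	4	5	0	0	1	0
cit	6	8	7	0	0	1	0
akg	5	6	5	0	0	1	0
succ	4	6	4	0	0	1	0
mal	4	6	5	0	0	1	0
glx	2	2	3	0	0	1	0
hexose	6	12	6	0	0	1	0
val	5	11	2	1	0	1	0
cys	3	7	2	1	1	1	0
h2s	0	2	0	0	1	1	0
aaa	6	11	4	1	0	1	0
acv	14	25	6	3	1	1	0
ipn	14	21	6	3	1	1	0
paacoa	8	8	2	0	0	1	0
o2	0	0	2	0	0	1	0
co2	1	0	2	0	0	1	0
h2o	0	2	1	0	0	1	0
nh3	0	3	0	1	0	1	0
h2so4	0	2	4	0	1	1	0
paa	8	8	2	0	0	1	0
peng	16	18	4	2	1	1	0
ohpaa	8	8	3	0	0	1	0
opc	6	9	3	1	0	1	0
6apa	8	12	3	2	1	1	0
8hpa	9	12	5	2	1	1	0
biomass	1	1.8	0.5	0.2	0	1	0
nadh	0	2	0	0	0	1	1
nadph	0	2	0	0	0	1	1
atp	0	0	0	0	0	1	1
ethanol_ext	2	6	1	0	0	0	0
o2_ext	0	0	2	0	0	0	0
co2_ext	1	0	2	0	0	0	0
nh3_ext	0	3	0	1	0	0	0
h2so4_ext	0	2	4	0	1	0	0
h2o_ext	0	2	1	0	0	0	0
paa_ext	8	8	2	0	0	0	0
peng_ext	16	18	4	2	1	0	0
ohpaa_ext	8	8	3	0	0	0	0
opc_ext	6	9	3	1	0	0	0
6apa_ext	8	12	3	2	1	0	0
8hpa_ext	9	12	5	2	1	0	0
biomass_ext	1	1.8	0.5	0.2	0	0	0
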