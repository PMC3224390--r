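reaction_id	equation	reversible	measured
t_eth	1 ethanol_ext -> 1 ethanol	0	1
t_o2	1 o2_ext -> 1 o2	0	1
t_co2	1 co2 -> 1 co2_ext	0	1
t_nh3	1 nh3_ext -> 1 nh3	0	0
t_h2so4	1 h2so4_ext -> 1 h2so4	0	0
t_h2o	1 h2o -> 1 h2o_ext	1	0
t_paa	1 paa_ext -> 1 paa	0	1
t_peng	1 peng -> 1 peng_ext	0	1
t_ohpaa	1 ohpaa -> 1 ohpaa_ext	0	1
t_opc	1 opc -> 1 opc_ext	0	1
t_6apa	1 6apa -> 1 6apa_ext	0	1
t_8hpa	1 8hpa -> 1 8hpa_ext	0	1
t_x	1 biomass -> 1 biomass_ext	0	1
adh	1 ethanol -> 1 acald + 1 nadh	1	0
aldh	1 acald + 1 h2o -> 1 ac + 1 nadh	0	0
acs	1 ac + 2 atp -> 1 accoa	0	0
mae	1 mal -> 1 pyr + 1 co2 + 1 nadph	0	0
cs	1 accoa + 1 oaa -> 1 cit	0	0
idh	1 cit -> 1 akg + 1 co2 + 1 nadh	0	0
akgdh	1 akg + 1 h2o -> 1 succ + 1 co2 + 1 nadh + 1 atp	0	0
sdh	1 succ + 1 h2o -> 1 mal + 1 nadh	0	0
mdh	1 mal -> 1 oaa + 1 nadh	1	0
icl	1 cit -> 1 succ + 1 glx	0	0
mals	1 glx + 1 accoa -> 1 mal	0	0
gng	2 oaa + 2 nadh + 6 atp -> 1 hexose + 2 co2	0	0
ppp	1 hexose + 6 h2o -> 6 co2 + 12 nadph	0	0
oxp	1 nadh + 0.5 o2 -> 1 h2o + 1.5 atp	0	0
vals	2 pyr + 1 nh3 + 2 nadph -> 1 val + 1 co2 + 2 h2o	0	0
cyss	0.5 hexose + 1 nh3 + 1 h2s -> 1 cys + 1 h2o + 1 nadh	0	0
sra	1 h2so4 + 2 atp + 4 nadph -> 1 h2s + 4 h2o	0	0
aaas	1 akg + 1 accoa + 1 nh3 -> 1 aaa + 1 co2 + 1 h2o	0	0
acvs	1 aaa + 1 cys + 1 val + 3 atp -> 1 acv + 2 h2o	0	0
ipns	1 acv + 1 o2 -> 1 ipn + 2 h2o	0	0
pcl	1 paa + 2 atp -> 1 paacoa	0	0
aat	1 ipn + 1 paacoa -> 1 peng + 1 aaa	0	0
iah	1 ipn + 1 h2o -> 1 6apa + 1 aaa	0	0
hpas	1 6apa + 1 co2 -> 1 8hpa	0	0
opcs	1 aaa -> 1 opc + 1 h2o	0	0
pah	1 paa + 1 o2 + 1 nadph -> 1 ohpaa + 1 h2o	0	0
bio	0.08 hexose + 0.11 accoa + 0.05 pyr + 0.03 akg + 0.2 nh3 + 0.21 nadph + 2.5 atp -> 1 biomass + 0.5 h2o	0	0
matp	1 atp ->	0	0
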