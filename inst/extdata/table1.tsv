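run	mu_max_batch_h	qp_max_mmol_cmol_h	qp_at_subcultivation_mmol_cmol_h
chemostat-1	0.088	0.52	NA
chemostat-2	0.086	0.52	NA
chemostat-3	NA	0.52	NA
chemostat-4	0.089	0.54	NA
sub-chemostat-4.1	0.109	0.11	0.04
sub-chemostat-4.2	0.112	0.10	0.04
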