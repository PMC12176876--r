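reaction_id	description	role	control_flux	pd_flux	rescued_flux	printed_improvement
ATPS4mi	ATP synthase	energy	8.5862	9.48623	9.5930	Yes
EX_gln_L[e]	Exchange of L-Glutamine	exchange	-17.0832	-16.8687	-17.4678	Yes
EX_lys_L[e]	Exchange of L-Lysine	exchange	-19.2610	-18.9466	-19.7937	Yes
EX_his_L[e]	Exchange of L-Histidine	exchange	-6.9666	-5.9576	-6.1757	Yes
EX_glyc_R[e]	Exchange of Glyceric acid	exchange	0.3131	0.2876	0.2876	No
EX_lac_L[e]	Exchange of L-Lactic acid	exchange	-1.1569	-0.6983	-0.7279	Yes
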