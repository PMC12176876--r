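metabolite	reaction_id	directions	control_flux	pd_flux	printed_change	printed_consistency	blocked
Dopamine	EX_dopa[e]	increased	0	0	No excrete	-	TRUE
D-Glucose	EX_glc_D[e]	increased;decreased	-0.4825	-0.2792	Lower uptake	Yes	FALSE
L-Tryptophan	EX_trp_L[e]	decreased	-0.8357	-0.8357	Same	-	FALSE
L-Methionine	EX_met_L[e]	increased	-1.1715	-1.2528	Higher uptake	No	FALSE
L-Asparagine	EX_asn_L[e]	increased	0.4867	0.4867	Same	-	FALSE
Ornithine	EX_orn[e]	increased	25.3657	25.3657	Same	-	FALSE
L-Glutamine	EX_gln_L[e]	increased;decreased	-17.0832	-16.8687	Lower uptake	Yes	FALSE
L-Lysine	EX_lys_L[e]	increased	-19.2610	-18.9466	Lower uptake	Yes	FALSE
L-Histidine	EX_his_L[e]	increased	-6.9666	-5.9576	Lower uptake	Yes	FALSE
L-Isoleucine	EX_ile_L[e]	increased	-8.4975	-8.4975	Same	-	FALSE
L-Pipecolic acid	EX_Lpipecol[e]	decreased	0.8811	1.0950	Higher excrete	No	FALSE
Citric acid	EX_cit[e]	increased	0.2540	0.2540	Same	-	FALSE
Ketoleucine	EX_4mop[e]	increased	-0.5428	-0.5550	Higher uptake	No	FALSE
Putrescine	EX_ptrc[e]	increased	-0.1268	-0.1268	Same	-	FALSE
Glyceric acid	EX_glyc_R[e]	decreased	0.3131	0.2876	Lower excrete	Yes	FALSE
Urea	EX_urea[e]	decreased	0.0624	0.0882	Higher excrete	No	FALSE
L-Lactic acid	EX_lac_L[e]	increased	-1.1569	-0.6983	Lower uptake	Yes	FALSE
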