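metabolite	reaction_id	directions	control_flux	pd_flux	printed_change	printed_consistency	blocked
Dopamine	EX_dopa[e]	increased	1.0826	0.3840	Lower excrete	No	FALSE
D-Glucose	EX_glc_D[e]	increased;decreased	-0.7525	-0.3146	Lower uptake	Yes	FALSE
L-Tryptophan	EX_trp_L[e]	decreased	-0.8357	-0.8357	Same	-	FALSE
L-Methionine	EX_met_L[e]	increased	-1.8909	-1.2779	Lower uptake	Yes	FALSE
L-Asparagine	EX_asn_L[e]	increased	0.4867	0.4867	Same	-	FALSE
Ornithine	EX_orn[e]	increased	25.3657	25.3657	Same	-	FALSE
L-Glutamine	EX_gln_L[e]	increased;decreased	-16.6588	-16.6238	Lower uptake	Yes	FALSE
L-Lysine	EX_lys_L[e]	increased	-15.0386	-14.9391	Lower uptake	Yes	FALSE
L-Histidine	EX_his_L[e]	increased	-6.3213	-7.2753	Higher uptake	No	FALSE
L-Isoleucine	EX_ile_L[e]	increased	-8.4975	-8.4975	Same	-	FALSE
L-Pipecolic acid	EX_Lpipecol[e]	decreased	0	0	Same	-	FALSE
Citric acid	EX_cit[e]	increased	0.2540	0.2540	Same	-	FALSE
Ketoleucine	EX_4mop[e]	increased	-0.1546	-0.1951	Higher uptake	No	FALSE
Putrescine	EX_ptrc[e]	increased	-0.1268	-0.1268	Same	-	FALSE
Glyceric acid	EX_glyc_R[e]	decreased	0.2876	0.2876	Same	-	FALSE
Urea	EX_urea[e]	decreased	0.2291	0.1597	Lower excrete	Yes	FALSE
L-Lactic acid	EX_lac_L[e]	increased	-0.3649	-0.2427	Lower uptake	Yes	FALSE
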