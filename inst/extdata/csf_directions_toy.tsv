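metabolite	reaction_id	directions	citations	blocked
D-Glucose	EX_glc_D[e]	increased;decreased	csf-meta	FALSE
L-Lactic acid	EX_lac_L[e]	increased	csf-meta	FALSE
Urea	EX_urea[e]	decreased	csf-meta	FALSE
L-Histidine	EX_his_L[e]	increased	csf-meta	FALSE
L-Lysine	EX_lys_L[e]	increased	csf-meta	FALSE
L-Methionine	EX_met_L[e]	increased	csf-meta	FALSE
L-Glutamine	EX_gln_L[e]	increased;decreased	csf-meta	FALSE
Ornithine	EX_orn[e]	increased	csf-meta	FALSE
Putrescine	EX_ptrc[e]	increased	csf-meta	FALSE
Dopamine	EX_dopa[e]	increased	csf-meta	FALSE
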