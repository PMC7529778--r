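index,variation_pct,direction
HR,13.00,increase
SV,-18.32,decrease
V_lved,-9.30,decrease
V_lves,4.75,increase
EF,-9.93,decrease
CO,-7.58,decrease
MAP,-9.92,decrease
P_AA_syst,-13.39,decrease
P_AA_dias,-6.90,decrease
PP_AA,-22.30,decrease
AI_AA,-41.18,decrease
SW_min,-19.29,decrease
TTI_min,-8.38,decrease
RPP,-1.91,decrease
CVP,-5.08,decrease
pulmonary_artery_volume,14.61,increase
pulmonary_vein_volume,21.39,increase
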