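pgg_ug_ml,v_plus_nm_s,k_plus_1e9_l_cell_s,v_a_nm_s,k_a_1e9_l_cell_s
0,1.60,0.98,0.55,2.9
6.25,2.10,1.13,0.52,2.3
12.5,2.38,1.17,0.49,2.2
25,2.52,1.28,0.42,2.04
50,2.70,1.36,0.35,1.06
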