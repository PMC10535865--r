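treatment,ic50_sensitive_um,ic50_resistant_um,resistance_index,reversal_index
dox,0.64,4.54,7.1,1
dox_pgg12.5,0.65,3.30,5.2,1.4
dox_pgg25,0.60,0.95,1.5,4.7
dox_pgg50,0.63,0.22,0.3,23.7
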