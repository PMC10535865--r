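compound,site,e_vdw,e_elect,g_polar,g_nonpolar,minus_tds,dg_bind
verapamil,substrate,-57.36,-9.45,31.87,-8.21,9.28,-33.87
tariquidar,substrate,-76.09,-25.31,56.04,-10.30,10.02,-45.64
pgg,substrate,-85.52,-87.62,115.17,-14.20,29.10,-43.07
pgg,atp,-84.72,-65.65,75.80,-13.31,16.44,-71.45
atp,atp,-41.73,-519.36,495.84,-6.55,50.60,-21.21
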