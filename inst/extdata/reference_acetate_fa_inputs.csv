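# Published inputs, 2-14C-acetate labeling of fatty acids by isolated
# plastids (1-h labeling). c2_units: acetate units per chain.
pool,incorporation_pmol,content_nmol_per_mg_chl,c2_units
14:0,0.70,6.19,7
16:0,5.77,1078,8
18:0,3.68,293,9
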