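# Published inputs, 2-13C-acetate labeling of fatty acids by isolated
# plastids (1 h): pool contents and highly labeled (p > 0.5) isotopomer
# fractions. NA = not detected.
pool,content_nmol_per_mg_chl,labeled_fraction_pct
14:0,6.19,2.28
16:0,1078.3,0.49
18:0,293.2,3.72
18:1,360.9,NA
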