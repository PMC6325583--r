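# Published inputs, 13C-bicarbonate labeling of MGDG moieties (1 h):
# pool contents and highly labeled (p > 0.5) isotopomer fractions, for
# intact cells and isolated plastids. NA = not detected.
pool,system,content_nmol_per_mg_chl,labeled_fraction_pct
glycerol,intact,400.92,6.12
galactose,intact,400.92,8.80
16:0,intact,294.44,7.08
18:2,intact,488.41,NA
glycerol,isolated,400.92,0.55
galactose,isolated,400.92,3.43
16:0,isolated,294.44,NA
18:2,isolated,488.41,NA
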