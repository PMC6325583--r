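# Published inputs, 14C-bicarbonate labeling of plastid membrane lipids
# (isolated plastids, 1-h labeling).
# incorporation_pmol: pmol 14C per mg chlorophyll per h (mean of n = 3).
# content_nmol_per_mg_chl: lipid pool size per mg chlorophyll.
# carbon_number: carbons per molecule assuming C18/C16 species.
pool,incorporation_pmol,content_nmol_per_mg_chl,carbon_number
MGDG,3.58,401,43
DGDG,0.50,439,49
SQDG,0.24,234,43
PG,0.60,159,40
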