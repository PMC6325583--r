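# Published derived cells, 14C-bicarbonate lipid-class table.
# column: derived column of build_rate_table(); value: printed value;
# digits: printed decimal places; anomaly: cell known not to recompute
# from its own printed inputs (rounding in the source).
pool,column,value,digits,anomaly,note
MGDG,carbon_content,17.2,1,FALSE,
DGDG,carbon_content,21.5,1,FALSE,
SQDG,carbon_content,10.1,1,FALSE,
PG,carbon_content,6.36,2,FALSE,
MGDG,specific_radioactivity,0.208,3,FALSE,
DGDG,specific_radioactivity,0.023,3,FALSE,
SQDG,specific_radioactivity,0.023,3,TRUE,recomputes to 0.024 from printed inputs
PG,specific_radioactivity,0.094,3,FALSE,
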