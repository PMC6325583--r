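# Published derived cells, 13C-bicarbonate MGDG-moiety table.
# Not-detected cells are absent (excluded from diffs).
pool,system,column,value,digits,anomaly,note
glycerol,intact,incorporation_rate,24.55,2,TRUE,recomputes to 24.54 from printed inputs
galactose,intact,incorporation_rate,35.28,2,FALSE,
16:0,intact,incorporation_rate,20.85,2,FALSE,
glycerol,intact,turnover_rate,0.063,3,FALSE,
galactose,intact,turnover_rate,0.092,3,FALSE,
16:0,intact,turnover_rate,0.073,3,FALSE,
glycerol,isolated,incorporation_rate,2.21,2,FALSE,
galactose,isolated,incorporation_rate,13.63,2,TRUE,recomputes to 13.75 from printed inputs
glycerol,isolated,turnover_rate,0.006,3,FALSE,
galactose,isolated,turnover_rate,0.035,3,FALSE,
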