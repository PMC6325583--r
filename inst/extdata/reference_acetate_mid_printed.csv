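# Published derived cells, 2-13C-acetate fatty-acid MID table.
pool,column,value,digits,anomaly,note
14:0,incorporation_rate,0.14,2,FALSE,
16:0,incorporation_rate,5.25,2,TRUE,recomputes to 5.28 from printed inputs
18:0,incorporation_rate,10.91,2,FALSE,
14:0,turnover_rate,0.023,3,FALSE,
16:0,turnover_rate,0.005,3,FALSE,
18:0,turnover_rate,0.038,3,FALSE,
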