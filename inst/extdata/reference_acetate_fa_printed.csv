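# Published derived cells, 2-14C-acetate fatty-acid table.
pool,column,value,digits,anomaly,note
14:0,c2_content,43.3,1,FALSE,
16:0,c2_content,8624,0,FALSE,
18:0,c2_content,2637,0,FALSE,
14:0,specific_radioactivity,16.2,1,FALSE,
16:0,specific_radioactivity,0.669,3,FALSE,
18:0,specific_radioactivity,1.396,3,FALSE,
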