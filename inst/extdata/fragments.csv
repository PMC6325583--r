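# Measured GC-MS fragments.
# n_labelable: tracer-reachable backbone positions (all carbons for
#   bicarbonate labeling of sugars/glycerol; even-numbered acyl carbons,
#   i.e. one per C2 unit, for [2-13C]acetate labeling of fatty acids).
# n_derivatization_carbons: carbons added at natural abundance by
#   derivatization (FAME methyl = 1; methyl glycoside + 4 TMS = 13;
#   3 TMS on glycerol = 9). The default carbon-only backbone analysis
#   sets these to zero.
name,n_analyte_carbons,n_labelable,n_derivatization_carbons
galactose,6,6,13
glycerol,3,3,9
14:0,14,7,1
16:0,16,8,1
18:0,18,9,1
18:1,18,9,1
18:2,18,9,1
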