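# Calibration scenario mirroring the intact-cell 13C-bicarbonate labeling
# kinetics of the MGDG moieties: 1-h labeling, fully labelable backbones,
# turnover rates equal to the published intact-cell estimates. n_ions = 0
# gives the noiseless limit; raise it (e.g. 1e5) for ion-counting noise.
fragments:
  - name: galactose
    n_analyte_carbons: 6
    n_labelable: 6
    n_derivatization_carbons: 0
  - name: glycerol
    n_analyte_carbons: 3
    n_labelable: 3
    n_derivatization_carbons: 0
  - name: "16:0"
    n_analyte_carbons: 16
    n_labelable: 16
    n_derivatization_carbons: 0
turnover_rates:
  galactose: 0.092
  glycerol: 0.063
  "16:0": 0.073
p_label:
  galactose: 0.99
  glycerol: 0.99
  "16:0": 0.99
pool_contents:
  galactose: 400.92
  glycerol: 400.92
  "16:0": 294.44
timepoints: [1.0]
n_ions: 0
p_nat: 0.0107
seed: 1
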