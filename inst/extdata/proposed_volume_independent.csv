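"metric","current","proposed"
"d95_pct",100,98.2
"v100_pct",95,91.4
"v90_pct",99,98.8
"v105_pct_of_ptv",15,12.9
"rx_over_dmax_min",0.6,0.59
"rx_over_dmax_max",0.9,0.89
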