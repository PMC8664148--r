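"ptv_cc","ci_variation_current","ci_deviation_current","ci_variation_proposed","ci_deviation_proposed","d2cm_variation_current","d2cm_deviation_current","d2cm_variation_proposed","d2cm_deviation_proposed","r50_variation_current","r50_deviation_current","r50_variation_proposed","r50_deviation_proposed"
13.2,1.2,1.5,1.12,1.41,50,58,49,57,4.7,5.8,4.66,5.75
22,1.2,1.5,1.12,1.41,54,63,53,62,4.5,5.5,4.46,5.45
34,1.2,1.5,1.12,1.41,58,68,57,67,4.3,5.3,4.26,5.25
50,1.2,1.5,1.12,1.41,62,77,61,76,4,5,3.96,4.96
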