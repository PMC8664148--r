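"ptv_cc","ci_none","ci_minor_upper","r50_none","r50_minor_upper","d2cm_none","d2cm_minor_upper"
1.8,1.2,1.5,6,7.5,50,57
3.8,1.2,1.5,6,6.5,50,57
7.4,1.2,1.5,5,6,50,58
13.2,1.2,1.5,4.7,5.8,50,58
22,1.2,1.5,4.5,5.5,54,63
34,1.2,1.5,4.3,5.3,58,68
50,1.2,1.5,4,5,62,77
70,1.2,1.5,4,4.8,66,86
95,1.2,1.5,3,4.4,70,89
126,1.2,1.5,3,4,73,91
163,1.2,1.5,3,3.7,77,94
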