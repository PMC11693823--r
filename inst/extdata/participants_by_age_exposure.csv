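catalan_exposure,age_10_14,age_14_18,age_18_22,age_22_26,age_26_30,age_30_34
75-100,18,23,36,38,20,7
50-75,8,13,30,41,18,1
25-50,10,17,45,29,17,0
0-25,7,11,21,17,8,1
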