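adherence_cat,exac_cat,n
<=50,0,374
51-60,0,63
61-70,0,71
71-80,0,59
81-90,0,107
91-100,0,227
<=50,1,33
51-60,1,7
61-70,1,5
71-80,1,11
81-90,1,9
91-100,1,26
<=50,2,5
51-60,2,1
61-70,2,1
71-80,2,1
81-90,2,2
91-100,2,6
<=50,3,0
51-60,3,0
61-70,3,0
71-80,3,0
81-90,3,0
91-100,3,1
<=50,>=4,2
51-60,>=4,0
61-70,>=4,0
71-80,>=4,0
81-90,>=4,0
91-100,>=4,1
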