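adherence_cat,saba_cat,n
<=50,0,181
51-60,0,24
61-70,0,30
71-80,0,26
81-90,0,56
91-100,0,107
<=50,1-2,179
51-60,1-2,38
61-70,1-2,26
71-80,1-2,31
81-90,1-2,46
91-100,1-2,120
<=50,3-6,47
51-60,3-6,9
61-70,3-6,19
71-80,3-6,13
81-90,3-6,15
91-100,3-6,27
<=50,7-12,6
51-60,7-12,0
61-70,7-12,2
71-80,7-12,1
81-90,7-12,0
91-100,7-12,7
<=50,>=13,1
51-60,>=13,0
61-70,>=13,0
71-80,>=13,0
81-90,>=13,1
91-100,>=13,0
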