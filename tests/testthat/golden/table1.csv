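variable,level,n,pct,mean,sd
sex,male,410,40.433925049309664,NA,NA
sex,female,604,59.566074950690336,NA,NA
age,12-17,67,6.607495069033531,NA,NA
age,18-39,218,21.499013806706113,NA,NA
age,40-54,297,29.28994082840237,NA,NA
age,55-64,185,18.244575936883628,NA,NA
age,65+,247,24.358974358974358,NA,NA
comedication,0,121,11.93293885601578,NA,NA
comedication,1,202,19.921104536489153,NA,NA
comedication,2,193,19.03353057199211,NA,NA
comedication,>2,498,49.112426035502956,NA,NA
comorbidity,0,345,34.023668639053255,NA,NA
comorbidity,1,244,24.06311637080868,NA,NA
comorbidity,2,158,15.581854043392505,NA,NA
comorbidity,>2,267,26.331360946745562,NA,NA
gina_class,1,2,0.19723865877712032,NA,NA
gina_class,2,151,14.891518737672584,NA,NA
gina_class,3,350,34.51676528599606,NA,NA
gina_class,4,480,47.337278106508876,NA,NA
gina_class,5,31,3.057199211045365,NA,NA
ics_adherence,<=50,414,40.90909090909091,NA,NA
ics_adherence,51-60,71,7.015810276679842,NA,NA
ics_adherence,61-70,77,7.608695652173913,NA,NA
ics_adherence,71-80,71,7.015810276679842,NA,NA
ics_adherence,81-90,118,11.660079051383399,NA,NA
ics_adherence,91-100,261,25.790513833992094,NA,NA
saba,0,424,41.814595660749504,NA,NA
saba,1-2,442,43.58974358974359,NA,NA
saba,3-6,130,12.820512820512821,NA,NA
saba,7-12,16,1.5779092702169626,NA,NA
saba,>=13,2,0.19723865877712032,NA,NA
exacerbations,0,903,89.05325443786982,NA,NA
exacerbations,1,91,8.974358974358974,NA,NA
exacerbations,2,16,1.5779092702169626,NA,NA
exacerbations,3,1,0.09861932938856016,NA,NA
exacerbations,>=4,3,0.2958579881656805,NA,NA
asthma_control,FALSE,84,50.29940119760479,NA,NA
asthma_control,TRUE,83,49.70059880239521,NA,NA
cma7_pct,mean_sd,1012,NA,61.62579105380246,28.326525205990233
saba_n,mean_sd,1014,NA,1.1962524654832347,1.6313639178148782
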