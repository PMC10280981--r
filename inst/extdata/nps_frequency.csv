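symptom,group,count,percent
delusions,ADMCI,10,8.7
delusions,ALS,1,2.5
delusions,FTD,7,13.7
delusions,PD,4,2.9
delusions,CVD,11,7.6
hallucinations,ADMCI,5,4.3
hallucinations,ALS,1,2.5
hallucinations,FTD,2,3.9
hallucinations,PD,13,9.5
hallucinations,CVD,3,2.1
agitation,ADMCI,33,28.2
agitation,ALS,9,22.5
agitation,FTD,20,39.2
agitation,PD,24,17.4
agitation,CVD,37,25.5
depression,ADMCI,38,32.5
depression,ALS,15,37.5
depression,FTD,18,36.0
depression,PD,52,37.7
depression,CVD,38,26.2
anxiety,ADMCI,30,25.6
anxiety,ALS,7,17.5
anxiety,FTD,24,47.1
anxiety,PD,30,21.7
anxiety,CVD,22,15.2
euphoria,ADMCI,6,5.1
euphoria,ALS,2,5.0
euphoria,FTD,8,15.7
euphoria,PD,4,2.9
euphoria,CVD,5,3.4
apathy,ADMCI,44,38.3
apathy,ALS,11,27.5
apathy,FTD,28,56.0
apathy,PD,32,23.2
apathy,CVD,33,22.8
disinhibition,ADMCI,27,23.1
disinhibition,ALS,3,7.5
disinhibition,FTD,22,44.0
disinhibition,PD,17,12.3
disinhibition,CVD,21,14.5
irritability,ADMCI,44,37.9
irritability,ALS,9,22.5
irritability,FTD,30,58.8
irritability,PD,38,27.5
irritability,CVD,55,38.2
aberrant_motor,ADMCI,15,12.8
aberrant_motor,ALS,5,12.8
aberrant_motor,FTD,16,31.4
aberrant_motor,PD,7,5.1
aberrant_motor,CVD,12,8.3
appetite,ADMCI,32,28.1
appetite,ALS,16,41.0
appetite,FTD,29,56.9
appetite,PD,38,27.5
appetite,CVD,33,22.8
nighttime,ADMCI,26,22.8
nighttime,ALS,10,26.3
nighttime,FTD,28,54.9
nighttime,PD,73,52.9
nighttime,CVD,49,34.0
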