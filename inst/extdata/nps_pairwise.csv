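symptom,group1,group2,printed_p
agitation,FTD,PD,0.003
anxiety,FTD,PD,0.001
anxiety,FTD,ALS,0.004
anxiety,FTD,CVD,<0.001
anxiety,ADMCI,CVD,0.043
apathy,FTD,PD,<0.001
apathy,FTD,ALS,0.001
apathy,FTD,CVD,<0.001
apathy,ADMCI,PD,0.013
apathy,ADMCI,CVD,0.009
appetite,FTD,ADMCI,<0.001
appetite,FTD,PD,<0.001
appetite,FTD,CVD,<0.001
appetite,ALS,CVD,0.026
disinhibition,FTD,CVD,<0.001
disinhibition,FTD,PD,<0.001
disinhibition,FTD,ALS,<0.001
disinhibition,ADMCI,PD,0.030
disinhibition,ADMCI,ALS,0.036
euphoria,FTD,PD,<0.001
irritability,FTD,PD,<0.001
irritability,FTD,ALS,<0.001
aberrant_motor,FTD,CVD,<0.001
aberrant_motor,FTD,PD,<0.001
aberrant_motor,ADMCI,PD,0.042
nighttime,FTD,ADMCI,<0.001
nighttime,PD,ADMCI,<0.001
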