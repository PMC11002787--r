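code,system,description,incident,prevalent,category
200001,medcode,Chronic obstructive pulmonary disease,true,true,
H3...,read_v2,Chronic obstructive pulmonary disease,true,true,
200002,medcode,Emphysema,true,true,
H32..,read_v2,Emphysema,true,true,
200003,medcode,COPD annual review,false,true,
66YM.,read_v2,COPD annual review,false,true,
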