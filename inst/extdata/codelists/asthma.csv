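code,system,description,incident,prevalent,category
100001,medcode,Asthma,true,true,
H33..,read_v2,Asthma,true,true,
100002,medcode,Allergic asthma,true,true,
H330.,read_v2,Allergic asthma,true,true,
100003,medcode,Asthma annual review,false,true,
663w.,read_v2,Asthma annual review,false,true,
100004,medcode,Asthma management plan given,false,true,
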