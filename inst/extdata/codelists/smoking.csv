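code,system,description,incident,prevalent,category
500001,medcode,Never smoked tobacco,false,false,never
1371.,read_v2,Never smoked tobacco,false,false,never
500002,medcode,Current smoker,false,false,current
137R.,read_v2,Current smoker,false,false,current
500003,medcode,Ex-smoker,false,false,ex
137S.,read_v2,Ex-smoker,false,false,ex
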