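code,system,description,incident,prevalent,category
600001,medcode,Body mass index,false,false,bmi
22K..,read_v2,Body mass index,false,false,bmi
600002,medcode,Body weight,false,false,weight
22A..,read_v2,Body weight,false,false,weight
600003,medcode,Standing height,false,false,height
229..,read_v2,Standing height,false,false,height
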