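code,system,description,incident,prevalent,category
700001,medcode,Forced expiratory volume in 1 second,false,false,fev1
339O.,read_v2,Forced expiratory volume in 1 second,false,false,fev1
700002,medcode,FEV1 percent of predicted,false,false,fev1_pct_predicted
339P.,read_v2,FEV1 percent of predicted,false,false,fev1_pct_predicted
700003,medcode,Spirometry pre-bronchodilation,false,false,pre_bronchodilation
339e.,read_v2,Spirometry pre-bronchodilation,false,false,pre_bronchodilation
700004,medcode,Spirometry post-bronchodilation,false,false,post_bronchodilation
339f.,read_v2,Spirometry post-bronchodilation,false,false,post_bronchodilation
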