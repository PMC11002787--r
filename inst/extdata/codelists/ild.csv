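code,system,description,incident,prevalent,category
300001,medcode,Idiopathic pulmonary fibrosis,true,true,ipf_narrow
H563.,read_v2,Idiopathic pulmonary fibrosis,true,true,ipf_narrow
300002,medcode,Pulmonary fibrosis,true,true,ipf_broad
H564.,read_v2,Pulmonary fibrosis,true,true,ipf_broad
300003,medcode,Hypersensitivity pneumonitis,true,true,exposure_related
H35y.,read_v2,Hypersensitivity pneumonitis,true,true,exposure_related
300004,medcode,Sarcoidosis,true,true,autoimmune_related
D864.,read_v2,Sarcoidosis,true,true,autoimmune_related
300005,medcode,Drug-induced interstitial lung disease,true,true,treatment_related
H57..,read_v2,Drug-induced interstitial lung disease,true,true,treatment_related
300006,medcode,Interstitial lung disease NOS,true,true,other
H565.,read_v2,Interstitial lung disease NOS,true,true,other
300007,medcode,ILD annual review,false,true,
66Yq.,read_v2,ILD annual review,false,true,
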