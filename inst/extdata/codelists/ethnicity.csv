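code,system,description,incident,prevalent,category,cat_ew2011,cat_sc2011,cat_harmonised
400001,medcode,Ethnic group: White British,false,false,White,White British,White Scottish or British,White
9S1..,read_v2,Ethnic group: White British,false,false,White,White British,White Scottish or British,White
400002,medcode,Ethnic group: White Irish,false,false,White,White Irish,White Irish,White
9S2..,read_v2,Ethnic group: White Irish,false,false,White,White Irish,White Irish,White
400003,medcode,Ethnic group: Indian,false,false,Asian,Indian,Indian,Asian or Asian British
9SA3.,read_v2,Ethnic group: Indian,false,false,Asian,Indian,Indian,Asian or Asian British
400004,medcode,Ethnic group: Pakistani,false,false,Asian,Pakistani,Pakistani,Asian or Asian British
9SA4.,read_v2,Ethnic group: Pakistani,false,false,Asian,Pakistani,Pakistani,Asian or Asian British
400005,medcode,Ethnic group: Chinese,false,false,Asian,Chinese,Chinese,Asian or Asian British
9SA9.,read_v2,Ethnic group: Chinese,false,false,Asian,Chinese,Chinese,Asian or Asian British
400006,medcode,Ethnic group: Black African,false,false,Black,African,African,Black or Black British
9SB1.,read_v2,Ethnic group: Black African,false,false,Black,African,African,Black or Black British
400007,medcode,Ethnic group: Black Caribbean,false,false,Black,Caribbean,Caribbean,Black or Black British
9SB2.,read_v2,Ethnic group: Black Caribbean,false,false,Black,Caribbean,Caribbean,Black or Black British
400008,medcode,Ethnic group: Mixed White and Asian,false,false,Mixed,White and Asian,Mixed or multiple,Mixed
9SC3.,read_v2,Ethnic group: Mixed White and Asian,false,false,Mixed,White and Asian,Mixed or multiple,Mixed
400009,medcode,Ethnic group: Any other ethnic group,false,false,Other,Any other ethnic group,Other ethnic group,Other
9SE..,read_v2,Ethnic group: Any other ethnic group,false,false,Other,Any other ethnic group,Other ethnic group,Other
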