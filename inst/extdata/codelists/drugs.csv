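code,system,description,incident,prevalent,category
90000101,dmd,Salbutamol 100micrograms/dose inhaler,false,false,SABA
c11a.,read_v2,Salbutamol 100micrograms/dose inhaler,false,false,SABA
0301011R0,bnf,Salbutamol 100micrograms/dose inhaler,false,false,SABA
90000201,dmd,Ipratropium bromide 20micrograms/dose inhaler,false,false,SAMA
c61a.,read_v2,Ipratropium bromide 20micrograms/dose inhaler,false,false,SAMA
0301020I0,bnf,Ipratropium bromide 20micrograms/dose inhaler,false,false,SAMA
90000301,dmd,Salmeterol 25micrograms/dose inhaler,false,false,LABA
c33a.,read_v2,Salmeterol 25micrograms/dose inhaler,false,false,LABA
0301011T0,bnf,Salmeterol 25micrograms/dose inhaler,false,false,LABA
90000401,dmd,Tiotropium 18micrograms inhalation capsules,false,false,LAMA
c67a.,read_v2,Tiotropium 18micrograms inhalation capsules,false,false,LAMA
0301020T0,bnf,Tiotropium 18micrograms inhalation capsules,false,false,LAMA
90000501,dmd,Beclometasone 100micrograms/dose inhaler,false,false,ICS
c82a.,read_v2,Beclometasone 100micrograms/dose inhaler,false,false,ICS
0302000C0,bnf,Beclometasone 100micrograms/dose inhaler,false,false,ICS
90000601,dmd,Salbutamol/ipratropium combination inhaler,false,false,SABA_SAMA
c69a.,read_v2,Salbutamol/ipratropium combination inhaler,false,false,SABA_SAMA
0301040S0,bnf,Salbutamol/ipratropium combination inhaler,false,false,SABA_SAMA
90000701,dmd,Salmeterol/fluticasone combination inhaler,false,false,LABA_ICS
c85a.,read_v2,Salmeterol/fluticasone combination inhaler,false,false,LABA_ICS
0302000N0,bnf,Salmeterol/fluticasone combination inhaler,false,false,LABA_ICS
90000801,dmd,Umeclidinium/vilanterol combination inhaler,false,false,LABA_LAMA
0301040U0,bnf,Umeclidinium/vilanterol combination inhaler,false,false,LABA_LAMA
90000901,dmd,Fluticasone/umeclidinium/vilanterol triple inhaler,false,false,triple_therapy
0301040T0,bnf,Fluticasone/umeclidinium/vilanterol triple inhaler,false,false,triple_therapy
90001001,dmd,Prednisolone 5mg tablets,false,false,OCS
fe61.,read_v2,Prednisolone 5mg tablets,false,false,OCS
0603020T0,bnf,Prednisolone 5mg tablets,false,false,OCS
90001101,dmd,Theophylline modified-release tablets,false,false,theophylline
c26a.,read_v2,Theophylline modified-release tablets,false,false,theophylline
0301030S0,bnf,Theophylline modified-release tablets,false,false,theophylline
90001201,dmd,Roflumilast 500micrograms tablets,false,false,PDE4
c97a.,read_v2,Roflumilast 500micrograms tablets,false,false,PDE4
0303000R0,bnf,Roflumilast 500micrograms tablets,false,false,PDE4
90001301,dmd,Amoxicillin 500mg capsules,false,false,antibiotics
e611.,read_v2,Amoxicillin 500mg capsules,false,false,antibiotics
0501013B0,bnf,Amoxicillin 500mg capsules,false,false,antibiotics
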