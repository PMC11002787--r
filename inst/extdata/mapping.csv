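source_system,source_code,target_system,target_code
medcode,100001,snomed_concept,195967001
medcode,100002,snomed_concept,389145006
medcode,100003,snomed_concept,394700004
medcode,100004,snomed_concept,810901000006
medcode,200001,snomed_concept,13645005
medcode,200002,snomed_concept,87433001
medcode,200003,snomed_concept,394703002
medcode,300001,snomed_concept,700250006
medcode,300002,snomed_concept,51615001
medcode,300003,snomed_concept,37471005
medcode,300004,snomed_concept,31541009
medcode,300005,snomed_concept,233724002
medcode,300006,snomed_concept,233703007
medcode,300007,snomed_concept,390898001
medcode,100001,read_v2,H33..
medcode,100002,read_v2,H330.
medcode,100003,read_v2,663w.
medcode,200001,read_v2,H3...
medcode,200002,read_v2,H32..
medcode,200003,read_v2,66YM.
medcode,300001,read_v2,H563.
medcode,300002,read_v2,H564.
medcode,300003,read_v2,H35y.
medcode,300004,read_v2,D864.
medcode,300005,read_v2,H57..
medcode,300006,read_v2,H565.
medcode,300007,read_v2,66Yq.
dmd,90000101,bnf,0301011R0
dmd,90000201,bnf,0301020I0
dmd,90000301,bnf,0301011T0
dmd,90000401,bnf,0301020T0
dmd,90000501,bnf,0302000C0
dmd,90000601,bnf,0301040S0
dmd,90000701,bnf,0302000N0
dmd,90000801,bnf,0301040U0
dmd,90000901,bnf,0301040T0
dmd,90001001,bnf,0603020T0
dmd,90001101,bnf,0301030S0
dmd,90001201,bnf,0303000R0
dmd,90001301,bnf,0501013B0
dmd,90000101,atc,R03AC02
dmd,90000201,atc,R03BB01
dmd,90000301,atc,R03AC12
dmd,90000401,atc,R03BB04
dmd,90000501,atc,R03BA01
dmd,90000601,atc,R03AL02
dmd,90000701,atc,R03AK06
dmd,90000801,atc,R03AL03
dmd,90000901,atc,R03AL08
dmd,90001001,atc,H02AB06
dmd,90001101,atc,R03DA04
dmd,90001201,atc,R03DX07
dmd,90001301,atc,J01CA04
atc,R03AC02,read_v2,c11a.
atc,R03BB01,read_v2,c61a.
atc,R03AC12,read_v2,c33a.
atc,R03BB04,read_v2,c67a.
atc,R03BA01,read_v2,c82a.
atc,R03AL02,read_v2,c69a.
atc,R03AK06,read_v2,c85a.
atc,H02AB06,read_v2,fe61.
atc,R03DA04,read_v2,c26a.
atc,R03DX07,read_v2,c97a.
atc,J01CA04,read_v2,e611.
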