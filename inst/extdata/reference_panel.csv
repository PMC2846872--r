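index,name,units,pre_mean,pre_sd,post_mean,post_sd,provenance,note
1,TP,g/L,79.82,5.08,78.02,5,screen,
2,ALB,g/L,52.19,2.49,50.47,2.42,consensus,
3,ALT,U/L,18.45,8.68,19.98,10.68,screen,
4,AST,U/L,22.38,5.07,21.14,4.97,screen,
5,TB,umol/L,12,4,12,4,null_default,synthetic null parameters
6,GLU,mmol/L,3.62,0.46,4.26,1.97,screen,
7,UN,mmol/L,5,1.2,5,1.2,null_default,synthetic null parameters
8,Cr,umol/L,79.44,9.34,78.4,8.23,screen,
9,UA,umol/L,330,60,330,60,null_default,synthetic null parameters
10,ALP,U/L,81.64,20.44,74.34,18.46,screen,
11,GGT,U/L,25,12,25,12,null_default,synthetic null parameters
12,CK,U/L,171.81,117.62,142.78,100.49,screen,
13,LDH,U/L,186.02,37.99,158.2,28,consensus,
14,HDL,mmol/L,1.25,0.28,1.25,0.28,null_default,synthetic null parameters
15,LDL,mmol/L,2.03,0.51,1.91,0.53,screen,
16,Ca,mmol/L,2.54,0.13,2.44,0.1,consensus,
17,PHOS,mmol/L,1.17,0.17,1.39,0.16,consensus,
18,Mg,mmol/L,0.88,0.07,0.88,0.07,null_default,synthetic null parameters
19,CHOL,mmol/L,4.12,0.64,3.9,0.69,screen,
20,TG,mmol/L,1.2,0.5,1.2,0.5,null_default,synthetic null parameters
21,TCO2,mmol/L,26,2.5,26,2.5,null_default,synthetic null parameters
22,UIBC,umol/L,32.21,9.89,36.5,10.84,screen,
23,Fe,umol/L,22.79,7.02,20.49,6.94,screen,
24,APOA1,g/L,1.35,0.22,1.35,0.22,null_default,synthetic null parameters
25,APOB,g/L,0.85,0.2,0.82,0.22,screen,
26,CK-MB,U/L,9.77,4.76,6.2,3.25,consensus,
27,APOA2,mg/dL,27.56,4.34,28.6,4.38,screen,
28,APOC2,mg/dL,2.56,1.22,2.87,1.42,screen,
29,APOC3,mg/dL,6.94,2.07,7.47,3.45,screen,
30,APOE,mg/dL,4,1.2,4,1.2,null_default,synthetic null parameters
31,LP(a),mg/dL,14.15,10.66,11.63,9.11,screen,
32,MAO,U/L,0.85,0.21,0.36,0.18,consensus,
33,PLIP,mmol/L,2.43,0.34,2.36,0.36,screen,
34,FRUC,umol/L,169.57,29.52,181.18,23,consensus,
35,DB,umol/L,3.5,1.5,3.5,1.5,null_default,synthetic null parameters
36,TBA,umol/L,169.57,29.52,181.18,23,screen,published row duplicates FRUC values; provenance suspect
37,ADA,U/L,11.5,2.23,10.38,2.09,screen,
38,Na,mmol/L,144.49,2.74,142.86,2.47,consensus,
39,K,mmol/L,4.05,0.33,4.35,0.36,consensus,
40,Cl,mmol/L,103,2.5,103,2.5,null_default,synthetic null parameters
41,TIBC,umol/L,54.99,8.68,56.99,7.56,screen,
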