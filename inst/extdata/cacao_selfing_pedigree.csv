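individual,parent,generation,family
TSH-1188,,S0,
PS-13.19,,S0,
CCN-51,,S0,
SIAL-169,,S0,
TSH-1188_S1_1,TSH-1188,S1,
TSH-1188_S1_2,TSH-1188,S1,
TSH-1188_S1_3,TSH-1188,S1,
CCN-51_S1_1,CCN-51,S1,
TSH-1188_S2_2_1,TSH-1188_S1_2,S2,A
TSH-1188_S2_2_2,TSH-1188_S1_2,S2,A
TSH-1188_S2_2_3,TSH-1188_S1_2,S2,A
TSH-1188_S2_2_4,TSH-1188_S1_2,S2,A
TSH-1188_S2_2_5,TSH-1188_S1_2,S2,A
TSH-1188_S2_2_6,TSH-1188_S1_2,S2,A
TSH-1188_S2_2_7,TSH-1188_S1_2,S2,A
TSH-1188_S2_2_8,TSH-1188_S1_2,S2,A
TSH-1188_S2_3_1,TSH-1188_S1_3,S2,B
TSH-1188_S2_3_2,TSH-1188_S1_3,S2,B
TSH-1188_S2_3_3,TSH-1188_S1_3,S2,B
TSH-1188_S2_3_4,TSH-1188_S1_3,S2,B
TSH-1188_S2_3_5,TSH-1188_S1_3,S2,B
TSH-1188_S2_3_6,TSH-1188_S1_3,S2,B
TSH-1188_S2_1_1,TSH-1188_S1_1,S2,C
TSH-1188_S2_1_3,TSH-1188_S1_1,S2,C
TSH-1188_S2_1_4,TSH-1188_S1_1,S2,C
TSH-1188_S2_1_5,TSH-1188_S1_1,S2,C
TSH-1188_S2_1_6,TSH-1188_S1_1,S2,C
TSH-1188_S2_1_7,TSH-1188_S1_1,S2,C
TSH-1188_S2_1_8,TSH-1188_S1_1,S2,C
PS-13.19_S1_1,PS-13.19,S1,D
PS-13.19_S1_2,PS-13.19,S1,D
PS-13.19_S1_3,PS-13.19,S1,D
PS-13.19_S1_4,PS-13.19,S1,D
PS-13.19_S1_5,PS-13.19,S1,D
PS-13.19_S1_6,PS-13.19,S1,D
PS-13.19_S1_7,PS-13.19,S1,D
PS-13.19_S1_8,PS-13.19,S1,D
PS-13.19_S1_9,PS-13.19,S1,D
CCN-51_S2_1_1,CCN-51_S1_1,S2,E
CCN-51_S2_1_2,CCN-51_S1_1,S2,E
CCN-51_S2_1_3,CCN-51_S1_1,S2,E
CCN-51_S2_1_4,CCN-51_S1_1,S2,E
CCN-51_S2_1_5,CCN-51_S1_1,S2,E
CCN-51_S2_1_6,CCN-51_S1_1,S2,E
CCN-51_S2_1_7,CCN-51_S1_1,S2,E
CCN-51_S2_1_8,CCN-51_S1_1,S2,E
CCN-51_S2_1_9,CCN-51_S1_1,S2,E
CCN-51_S2_1_10,CCN-51_S1_1,S2,E
SIAL-169_S1_1,SIAL-169,S1,F
SIAL-169_S1_2,SIAL-169,S1,F
SIAL-169_S1_3,SIAL-169,S1,F
SIAL-169_S1_5,SIAL-169,S1,F
SIAL-169_S1_6,SIAL-169,S1,F
SIAL-169_S1_7,SIAL-169,S1,F
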