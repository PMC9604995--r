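family,generation,individual,n_AA,n_AB,n_BB,obs_hom_printed,exp_hom_printed,z_printed,chi2_printed,sig_printed
A,S0,TSH-1188,812,1770,798,0.476,NA,NA,NA,NA
A,S1,TSH-1188_S1_2,924,1542,914,0.544,0.738,NA,660.74,**
A,S2,TSH-1188_S2_2_2,1193,1044,1141,0.691,0.772,-1.879,126.36,**
A,S2,TSH-1188_S2_2_1,1285,817,1267,0.757,0.772,-0.558,4.02,ns
A,S2,TSH-1188_S2_2_3,1317,746,1317,0.779,0.772,-0.126,1.09,ns
A,S2,TSH-1188_S2_2_7,1295,740,1343,0.781,0.772,-0.093,2.86,ns
A,S2,TSH-1188_S2_2_6,1285,729,1363,0.784,0.772,-0.030,5.85,ns
A,S2,TSH-1188_S2_2_5,1350,670,1359,0.802,0.772,0.319,17.21,**
A,S2,TSH-1188_S2_2_8,1387,580,1409,0.828,0.772,0.844,61.13,**
A,S2,TSH-1188_S2_2_4,1474,465,1440,0.862,0.772,1.523,157.3,**
B,S1,TSH-1188_S1_3,909,1536,934,0.545,0.738,NA,649.75,**
B,S2,TSH-1188_S2_3_3,1186,998,1193,0.704,0.773,-1.059,89.59,**
B,S2,TSH-1188_S2_3_4,1183,958,1238,0.716,0.773,-0.797,61.22,**
B,S2,TSH-1188_S2_3_1,1219,954,1206,0.718,0.773,-0.771,58.8,**
B,S2,TSH-1188_S2_3_5,1314,752,1311,0.777,0.773,0.529,0.71,ns
B,S2,TSH-1188_S2_3_2,1321,716,1339,0.788,0.773,0.760,4.46,ns
B,S2,TSH-1188_S2_3_6,1386,627,1366,0.814,0.773,1.338,34.32,**
C,S1,TSH-1188_S1_1,NA,NA,NA,0.545,0.738,NA,NA,NA
C,S2,TSH-1188_S2_1_1,1250,880,1249,0.740,0.773,-1.620,21.38,**
C,S2,TSH-1188_S2_1_7,1269,827,1282,0.755,0.773,-1.103,5.96,ns
C,S2,TSH-1188_S2_1_8,1335,702,1332,0.792,0.773,0.103,7.18,**
C,S2,TSH-1188_S2_1_6,1345,691,1344,0.796,0.773,0.233,10.32,**
C,S2,TSH-1188_S2_1_5,1335,665,1352,0.802,0.773,0.433,16.06,**
C,S2,TSH-1188_S2_1_4,1396,615,1368,0.818,0.773,0.975,40.58,**
C,S2,TSH-1188_S2_1_3,1316,589,1333,0.818,0.773,0.979,42.3,**
D,S0,PS-13.19,813,1721,846,0.491,NA,NA,NA,NA
D,S1,PS-13.19_S1_1,1051,1266,1063,0.625,0.745,-1.622,256.45,**
D,S1,PS-13.19_S1_5,1058,1184,1138,0.650,0.745,-1.182,164.2,**
D,S1,PS-13.19_S1_4,1123,1093,1158,0.676,0.745,-0.705,85.41,**
D,S1,PS-13.19_S1_7,1150,966,1226,0.711,0.745,-0.073,21.91,**
D,S1,PS-13.19_S1_6,1192,934,1252,0.724,0.745,0.155,8.85,**
D,S1,PS-13.19_S1_3,1215,888,1275,0.737,0.745,0.401,1.52,ns
D,S1,PS-13.19_S1_2,1211,829,1340,0.755,0.745,0.720,5.17,ns
D,S1,PS-13.19_S1_8,1262,791,1324,0.766,0.745,0.920,7.68,**
D,S1,PS-13.19_S1_9,751,619,1598,0.791,0.745,1.385,343.79,**
E,S0,CCN-51,767,1846,767,0.454,NA,NA,NA,NA
E,S1,CCN-51_S1_1,1239,874,1267,0.741,0.727,NA,3.9,ns
E,S2,CCN-51_S2_1_8,1415,510,1455,0.849,0.871,-1.793,14.06,**
E,S2,CCN-51_S2_1_5,1438,507,1434,0.850,0.871,-1.712,13.26,**
E,S2,CCN-51_S2_1_4,1443,445,1492,0.868,0.871,0.074,0.32,ns
E,S2,CCN-51_S2_1_3,1470,445,1465,0.868,0.871,0.074,0.54,ns
E,S2,CCN-51_S2_1_9,1452,444,1484,0.869,0.871,0.102,0.13,ns
E,S2,CCN-51_S2_1_6,1464,440,1476,0.870,0.871,0.217,0.11,ns
E,S2,CCN-51_S2_1_2,1436,439,1505,0.870,0.871,0.246,0.58,ns
E,S2,CCN-51_S2_1_1,1473,425,1480,0.874,0.871,0.641,0.51,ns
E,S2,CCN-51_S2_1_10,1483,411,1486,0.878,0.871,1.050,1.99,ns
E,S2,CCN-51_S2_1_7,1489,409,1480,0.879,0.871,1.101,2.5,ns
F,S0,SIAL-169,1610,106,1664,0.969,NA,NA,NA,NA
F,S1,SIAL-169_S1_1,1625,72,1683,0.979,0.984,-1.892,6.93,**
F,S1,SIAL-169_S1_7,1638,52,1690,0.985,0.984,-0.172,0.02,ns
F,S1,SIAL-169_S1_6,1642,49,1689,0.986,0.984,0.086,0.32,ns
F,S1,SIAL-169_S1_2,1644,45,1691,0.987,0.984,0.430,1.24,ns
F,S1,SIAL-169_S1_5,1641,41,1697,0.988,0.984,0.773,2.75,ns
F,S1,SIAL-169_S1_3,1643,41,1696,0.988,0.984,0.774,2.76,ns
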