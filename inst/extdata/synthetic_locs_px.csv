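# synthetic example localizations, units: camera px (pixel size 130 nm)
frame,x,y,photons,lpx,lpy
 304,13.59386,11.8311397, 1519,0.0342277,0.0364477
 504,13.67354,11.8745072,  636,0.0352153,0.0412457
1471,13.70073,11.8919241, 2575,0.0236330,0.0365350
5524,13.67540,11.8832112, 3268,0.0399619,0.0416146
9293,13.68145,11.8329442, 3457,0.0258168,0.0213314
6778,19.81559,15.4795240, 3552,0.0428135,0.0453358
1885,19.85992,15.4223821, 4243,0.0452170,0.0351073
9296,19.83732,15.4798681,    4,0.0403457,0.0222135
9148,19.84882,15.4794183, 2887,0.0323792,0.0347526
2647,10.62393, 6.9989230, 1398,0.0226282,0.0236245
3970,10.69395, 6.9417183,10426,0.0391710,0.0255353
6689,10.77145, 6.9873958, 3790,0.0376573,0.0244800
2852,10.71842, 7.0227259,  371,0.0296894,0.0276297
8006,10.72359, 7.0447809, 3636,0.0400760,0.0334934
1047,10.67939, 6.9768975, 5735,0.0263660,0.0447626
1164,19.37451, 0.1272403,   60,0.0242354,0.0266906
2447,19.28047, 0.1388030, 2298,0.0257630,0.0325470
4367,13.45282,16.2983034, 1685,0.0253492,0.0328012
 345,13.45349,16.2821573,  828,0.0248836,0.0208026
1462,13.39643,16.3175680, 1736,0.0245042,0.0355093
5331,13.43689,16.3205642, 1847,0.0327582,0.0305841
4852,13.46339,16.2737014, 6453,0.0334110,0.0328918
7331,13.43862,16.2832188, 3483,0.0272888,0.0321247
8122, 5.92551,-0.0298585, 5965,0.0288586,0.0485746
7595, 5.92616,-0.0104956, 4079,0.0338296,0.0329346
1751, 5.89471, 0.0285333, 4210,0.0267448,0.0445007
6286, 5.93195,-0.0441789, 2312,0.0469394,0.0397770
7103, 5.92951, 0.0587710,   45,0.0322805,0.0297855
2012, 5.96777,-0.0269970, 3497,0.0359461,0.0321389
2911, 7.19591, 3.9964936, 7355,0.0215065,0.0362798
2112, 7.14438, 3.9492611,   32,0.0317597,0.0357766
3794, 7.16466, 4.0189416, 4650,0.0502588,0.0300487
9895, 7.14733, 4.0519765,  161,0.0313312,0.0545287
7835, 7.19689, 3.9714074,  252,0.0252583,0.0573648
7074, 7.15757, 4.0149907, 1831,0.0348022,0.0301452
1893, 7.16816, 3.9429843,  623,0.0244710,0.0416301
2963, 7.21794, 4.0381705, 4760,0.0289105,0.0236886
1553, 3.49257,10.0306842, 1003,0.0278566,0.0305668
9745, 3.50350,10.0130865, 1561,0.0224940,0.0276134
3573, 3.50399,10.0722835, 2755,0.0358588,0.0244530
5537, 3.47171, 9.9568985,  456,0.0278573,0.0325792
1976, 3.50093, 9.9905848, 7575,0.0273540,0.0287400
8963,10.98633, 6.4596624, 2825,0.0336069,0.0254009
2128,10.99237, 6.4645352, 7435,0.0340119,0.0235686
8669,11.01401, 6.5290301,   40,0.0305133,0.0456927
2537,11.03338, 6.5062058, 7779,0.0369487,0.0352750
1811,11.02443, 6.4608004, 2671,0.0250640,0.0236227
2227,10.96255, 6.5006752,  219,0.0192658,0.0234844
8611,10.13207, 6.9404573, 1600,0.0346151,0.0239696
9814,10.16609, 6.9497836, 1038,0.0381399,0.0250416
9904,10.09533, 6.9355297, 2079,0.0279149,0.0181217
9445,10.08338, 6.9393277, 1241,0.0314443,0.0251812
1746, 3.88049,10.9127813, 6783,0.0186803,0.0189661
1525, 3.82431,10.9216863,  867,0.0456247,0.0335587
1679, 3.90646,10.8987486, 5637,0.0218321,0.0278447
1742, 3.88088,11.0134229, 2626,0.0389511,0.0462740
6344, 3.84574,10.9026831, 2084,0.0298011,0.0314050
4493, 3.86716,10.8755626, 1685,0.0176252,0.0272624
9184, 3.89902,10.9083924, 1368,0.0195274,0.0243862
5900,12.72964, 0.8072153, 2384,0.0323919,0.0278502
7827,12.73025, 0.8488555, 1631,0.0213602,0.0340443
7405,12.71629, 0.7725373, 8999,0.0414311,0.0255848
8058,12.76420, 0.8107579, 4423,0.0346828,0.0242061
7226,12.73196, 0.7910066, 2267,0.0195784,0.0303711
4515,12.76882, 0.8654056, 1469,0.0242438,0.0312531
2040,12.77978, 0.7894971,  402,0.0426522,0.0328245
4026,12.71233, 0.8463166, 3409,0.0235820,0.0268126
3052,12.75503, 0.7675551, 2495,0.0372534,0.0277076
7958,13.72358, 8.8964853,  118,0.0363474,0.0300635
8139,13.71645, 8.8788343,  289,0.0339188,0.0250815
 683,13.80264, 8.8928180,   88,0.0311442,0.0261831
7887,13.75317, 8.8335511, 4332,0.0233998,0.0258166
4711,12.83239,13.8641113,14897,0.0234307,0.0287169
1443,12.77464,13.8583040, 2887,0.0341988,0.0302328
9749,12.73580,13.8394299,10447,0.0388389,0.0384409
9597,12.82542,13.7748096, 4497,0.0283517,0.0279001
3758,12.78645,13.8434982,   96,0.0375731,0.0325926
3242, 7.15746,16.5029802,  416,0.0267161,0.0428006
2018, 7.17865,16.5071359, 2755,0.0328873,0.0464646
3756, 7.15301,16.4755236, 2047,0.0318943,0.0341472
 485, 7.18140,16.4739549, 7968,0.0344024,0.0358961
7972, 7.14631,16.4188789,  532,0.0333777,0.0300577
8604, 7.13539,16.4651778, 2134,0.0271138,0.0426515
9694, 7.18819,16.4606285, 4320,0.0220150,0.0297890
1671, 7.14468,16.4977402,  266,0.0380631,0.0555170
 181, 2.04520,12.1527308,  791,0.0287099,0.0246318
9258, 2.11405,12.1425296,  701,0.0464689,0.0223222
5597, 2.02488,12.1316349, 7784,0.0261997,0.0234235
7488, 2.04897,12.1333079,  494,0.0317669,0.0478795
 722, 2.00865,12.1368362, 1457,0.0363583,0.0451217
9333, 2.06933,12.1415742, 2634,0.0454732,0.0386204
9569, 2.00946,12.1341253, 1551,0.0375147,0.0262817
8599, 1.93019,19.5262184,  597,0.0397535,0.0327400
3172, 2.03425,19.5263439,  346,0.0320036,0.0366358
5827, 1.97277,19.5970244, 1144,0.0284313,0.0272123
9199, 1.98880,19.5531672,  666,0.0352908,0.0250712
 225, 3.66956,17.3091180, 2695,0.0260881,0.0301891
8625, 3.73675,17.3174007, 1783,0.0324335,0.0360898
2561, 3.62067,17.3031316, 1955,0.0350818,0.0320245
7314, 3.67618,17.2919326,  832,0.0191733,0.0324772
3672, 3.64650,17.3266181, 2025,0.0287436,0.0271998
7718, 4.60252, 9.7238760, 1046,0.0449045,0.0413224
3411, 4.57487, 9.6801675, 2401,0.0330156,0.0421728
3830, 4.51878, 9.7360908, 1863,0.0208046,0.0386988
9770, 4.55204, 9.6229939, 2667,0.0261808,0.0253608
2284, 4.56966, 9.6728661, 2095,0.0275065,0.0273391
6068, 1.56666,15.4994984,   13,0.0321988,0.0278432
2363, 1.64994,15.4657679, 6646,0.0262285,0.0258396
3912, 1.62703,15.5447663, 1801,0.0339920,0.0562981
4303, 1.52556,15.5182714,  882,0.0358887,0.0318397
9982, 1.60884,15.5401996, 3096,0.0343594,0.0314172
 784, 1.61668,15.4659735, 3259,0.0341161,0.0290183
3866, 1.60001,15.5063638,  967,0.0342635,0.0212156
2708,16.40715,18.5884114, 1047,0.0194532,0.0297365
5622,16.39676,18.6292432,  208,0.0258554,0.0448030
3109,16.52836,18.6437003, 1706,0.0455081,0.0256686
9580,16.44562,18.6306245, 5353,0.0275405,0.0273073
   0,16.40952,18.6448071,  790,0.0384167,0.0267903
2842,16.44200,18.5780945,  860,0.0226863,0.0313700
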