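id,alpha,theta,mu_xi,sigma2_xi
p01,0.6,0.1503,12.5862,0.9724
p02,0.6414,0.0841,13.9655,0.2
p03,0.6828,0.1338,8.4483,1.6483
p04,0.7241,0.109,9.1379,2.4207
p05,0.7655,0.1669,11.8966,2.9034
p06,0.8069,0.0883,14.3103,2.3241
p07,0.8483,0.1628,10.5172,1.4552
p08,0.8897,0.1834,15,2.6138
p09,0.931,0.171,6.0345,2.5172
p10,0.9724,0.1752,6.3793,1.1655
p11,1.0138,0.1793,8.7931,1.3586
p12,1.0552,0.1917,10.8621,2.7103
p13,1.0966,0.1131,11.2069,0.5862
p14,1.1379,0.0924,10.1724,1.2621
p15,1.1793,0.08,13.2759,0.6828
p16,1.2207,0.1297,7.069,2.131
p17,1.2621,0.0966,14.6552,1.5517
p18,1.3034,0.1007,8.1034,0.8759
p19,1.3448,0.1172,12.931,0.2966
p20,1.3862,0.1876,11.5517,0.7793
p21,1.4276,0.1048,12.2414,2.2276
p22,1.469,0.1421,13.6207,2.8069
p23,1.5103,0.2,5,0.4897
p24,1.5517,0.1959,5.6897,1.7448
p25,1.5931,0.1255,9.4828,1.8414
p26,1.6345,0.1462,6.7241,0.3931
p27,1.6759,0.1545,7.7586,3
p28,1.7172,0.1379,9.8276,1.069
p29,1.7586,0.1214,5.3448,1.9379
p30,1.8,0.1586,7.4138,2.0345
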