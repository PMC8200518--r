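# Photon mass attenuation coefficients for water (cm^2/g), density 0.998 g/cm^3.
# mu_total is the exact sum of the three process columns.
# Physics-anchored construction; see inst/extdata/MANIFEST.md.
energy_MeV,mu_photoelectric,mu_incoherent,mu_coherent,mu_total,mu_en
0.01,5.06758,0.213927,0.0487281,5.33024,4.944
0.012,2.8652,0.212368,0.0473927,3.12496,2.78296
0.015,1.41822,0.210084,0.0450404,1.67334,1.374
0.018,0.791706,0.207863,0.0423816,1.04195,0.769472
0.02,0.562818,0.206418,0.0405016,0.809738,0.5503
0.025,0.269614,0.202918,0.0356735,0.508206,0.272118
0.03,0.145073,0.199573,0.0309902,0.375636,0.1557
0.035,0.0844527,0.196372,0.0267131,0.307538,0.0993849
0.04,0.0520495,0.193308,0.0229554,0.268313,0.06947
0.045,0.0335099,0.19037,0.0197318,0.243612,0.0524277
0.05,0.022349,0.187552,0.017004,0.226905,0.04223
0.06,0.0108685,0.182246,0.0127884,0.205903,0.0319
0.07,0.00590818,0.177337,0.00981552,0.193061,0.0275781
0.076,0.00426806,0.174564,0.00845957,0.187292,0.026325
0.0762,0.00422394,0.174474,0.00841882,0.187117,0.0262946
0.08,0.00348456,0.172782,0.00769255,0.183959,0.02583
0.09,0.00218718,0.168542,0.00614755,0.176877,0.0253573
0.1,0.00144197,0.164586,0.005,0.171028,0.02546
0.125,0.00059671,0.155756,0.00318096,0.159534,0.0264315
0.15,0.000290183,0.148171,0.0021746,0.150636,0.02764
0.175,0.000157746,0.141574,0.00156834,0.1433,0.0287413
0.2,9.30362e-05,0.135772,0.00117832,0.137043,0.02967
0.25,3.84999e-05,0.126005,0.000727714,0.126771,0.0310367
0.3,1.87227e-05,0.118058,0.000489564,0.118566,0.03192
0.35,1.01778e-05,0.111426,0.000349723,0.111786,0.0324699
0.4,6.00273e-06,0.105776,0.000261155,0.106043,0.03279
0.45,3.76779e-06,0.100883,0.000201776,0.101089,0.0329483
0.5,2.48403e-06,0.0965862,0.000160161,0.0967488,0.03299
0.55,1.70406e-06,0.0927703,0.000129943,0.0929019,0.0329462
0.6,1.208e-06,0.0893484,0.000107352,0.089457,0.03284
0.7,6.56676e-07,0.0834377,7.65224e-05,0.0835149,0.0325018
0.8,3.87298e-07,0.0784803,5.70652e-05,0.0785378,0.03206
0.9,2.43099e-07,0.0742371,4.40501e-05,0.0742814,0.0315612
1,1.6027e-07,0.0705468,3.49428e-05,0.0705819,0.03103
1.1,1.09947e-07,0.067296,2.83367e-05,0.0673244,0.0304818
1.25,6.63225e-08,0.0630687,2.1393e-05,0.0630902,0.02965
1.4,4.2369e-08,0.0594509,1.66737e-05,0.0594676,0.0288363
1.5,3.2253e-08,0.0573093,1.43262e-05,0.0573237,0.02833
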