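# Photon mass attenuation coefficients for air (cm^2/g), density 0.001197 g/cm^3.
# mu_total is the exact sum of the three process columns.
# Physics-anchored construction; see inst/extdata/MANIFEST.md.
energy_MeV,mu_photoelectric,mu_incoherent,mu_coherent,mu_total,mu_en
0.01,5.0587,0.192536,0.0485939,5.29983,4.742
0.012,2.86018,0.191132,0.0472482,3.09856,2.68382
0.015,1.41574,0.189076,0.0448665,1.64968,1.334
0.018,0.790319,0.187078,0.0421656,1.01956,0.751216
0.02,0.561832,0.185777,0.0402543,0.787863,0.5389
0.025,0.269142,0.182627,0.0353519,0.487121,0.267968
0.03,0.144818,0.179616,0.0306178,0.355052,0.1537
0.035,0.0843047,0.176736,0.0263191,0.28736,0.0980655
0.04,0.0519583,0.173978,0.0225638,0.2485,0.06833
0.045,0.0334511,0.171334,0.0193584,0.224144,0.0512759
0.05,0.0223099,0.168798,0.0166571,0.207765,0.04098
0.06,0.0108494,0.164022,0.0125013,0.187373,0.03041
0.07,0.00589783,0.159604,0.00958299,0.175085,0.0259697
0.076,0.00426058,0.157108,0.00825491,0.169623,0.0246362
0.0762,0.00421654,0.157027,0.00821503,0.169459,0.0246026
0.08,0.00347845,0.155504,0.00750441,0.166487,0.02407
0.09,0.00218335,0.151689,0.00599419,0.159867,0.0233678
0.1,0.00143944,0.148128,0.00487365,0.154441,0.02325
0.125,0.000595664,0.140181,0.00309919,0.143876,0.023915
0.15,0.000289675,0.133355,0.00211826,0.135763,0.02496
0.175,0.000157469,0.127417,0.00152755,0.129102,0.0259152
0.2,9.28732e-05,0.122195,0.0011476,0.123435,0.02672
0.25,3.84325e-05,0.113405,0.000708695,0.114152,0.027928
0.3,1.86899e-05,0.106253,0.000476754,0.106748,0.02872
0.35,1.016e-05,0.100284,0.000340566,0.100635,0.0292096
0.4,5.99221e-06,0.0951989,0.000254314,0.0954592,0.02949
0.45,3.76118e-06,0.0907949,0.000196489,0.0909952,0.0296253
0.5,2.47967e-06,0.086928,0.000155964,0.0870864,0.02966
0.55,1.70108e-06,0.0834936,0.000126537,0.0836218,0.0296229
0.6,1.20588e-06,0.0804139,0.000104538,0.0805196,0.02953
0.7,6.55525e-07,0.0750943,7.45163e-05,0.0751695,0.0292234
0.8,3.86619e-07,0.0706326,5.55691e-05,0.0706886,0.02882
0.9,2.42673e-07,0.0668137,4.28951e-05,0.0668568,0.0283673
1,1.59989e-07,0.0634925,3.40266e-05,0.0635267,0.02789
1.1,1.09754e-07,0.0605667,2.75937e-05,0.0605944,0.0274018
1.25,6.62063e-08,0.0567621,2.0832e-05,0.056783,0.02666
1.4,4.22947e-08,0.0535061,1.62365e-05,0.0535224,0.0259275
1.5,3.21965e-08,0.0515786,1.39506e-05,0.0515926,0.02547
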