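# Photon mass attenuation coefficients for steel304 (cm^2/g), density 5.6 g/cm^3.
# mu_total is the exact sum of the three process columns.
# Physics-anchored construction; see inst/extdata/MANIFEST.md.
energy_MeV,mu_photoelectric,mu_incoherent,mu_coherent,mu_total
0.01,165.72,0.179767,0.219341,166.119
0.012,101.421,0.178456,0.216769,101.816
0.015,55.1803,0.176537,0.212001,55.5688
0.018,33.1812,0.174671,0.206232,33.5621
0.02,24.6243,0.173456,0.201894,24.9997
0.025,12.9781,0.170515,0.189676,13.3383
0.03,7.61809,0.167704,0.176121,7.96191
0.035,4.82096,0.165015,0.16198,5.14796
0.04,3.22622,0.16244,0.147885,3.53654
0.045,2.2546,0.159972,0.134306,2.54888
0.05,1.63106,0.157603,0.121554,1.91022
0.06,0.92502,0.153144,0.0991112,1.17728
0.07,0.569011,0.149019,0.0808699,0.7989
0.076,0.438148,0.146689,0.0717629,0.6566
0.0762,0.434495,0.146613,0.0714809,0.652589
0.08,0.371997,0.145191,0.0663684,0.583556
0.09,0.255016,0.141629,0.0549244,0.451569
0.1,0.181611,0.138304,0.0458834,0.365798
0.125,0.0881843,0.130884,0.0305023,0.249571
0.15,0.0488228,0.124511,0.0213839,0.194718
0.175,0.0296689,0.118967,0.0156628,0.164299
0.2,0.0193541,0.114091,0.011887,0.145332
0.25,0.0096181,0.105884,0.00742829,0.12293
0.3,0.00551324,0.0992062,0.00502882,0.109748
0.35,0.00348871,0.093633,0.00360572,0.100727
0.4,0.00238895,0.0888854,0.00269892,0.0939733
0.45,0.00174339,0.0847735,0.00208857,0.0886055
0.5,0.00133342,0.081163,0.00165966,0.0841561
0.55,0.00105932,0.0779564,0.00134761,0.0803633
0.6,0.000878594,0.075081,0.00111399,0.0770736
0.7,0.000684673,0.0701141,0.000794731,0.0715935
0.8,0.000596101,0.0659484,0.000592966,0.0671375
0.9,0.00055415,0.0623827,0.000457885,0.0633947
1,0.000535885,0.0592817,0.000363306,0.0601809
1.1,0.000530655,0.0565499,0.000294674,0.0573752
1.25,0.000535584,0.0529977,0.000222507,0.0537558
1.4,0.000547286,0.0499576,0.000173444,0.0506783
1.5,0.000556071,0.0481579,0.000149035,0.048863
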