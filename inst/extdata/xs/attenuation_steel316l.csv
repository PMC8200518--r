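# Photon mass attenuation coefficients for steel316l (cm^2/g), density 7.8 g/cm^3.
# mu_total is the exact sum of the three process columns.
# Physics-anchored construction; see inst/extdata/MANIFEST.md.
energy_MeV,mu_photoelectric,mu_incoherent,mu_coherent,mu_total
0.01,166.48,0.179611,0.224408,166.884
0.012,101.886,0.178302,0.221815,102.286
0.015,55.4334,0.176384,0.217007,55.8268
0.018,33.3334,0.17452,0.211185,33.7191
0.02,27.7331,0.173306,0.206806,28.1132
0.025,14.6168,0.170368,0.194458,14.9816
0.03,8.58011,0.167559,0.18074,8.92841
0.035,5.42982,0.164872,0.166406,5.7611
0.04,3.63371,0.162299,0.152093,3.9481
0.045,2.53939,0.159833,0.13828,2.8375
0.05,1.83711,0.157467,0.125284,2.11986
0.06,1.04189,0.153012,0.102354,1.29726
0.07,0.640907,0.14889,0.083657,0.873454
0.076,0.493511,0.146562,0.0743013,0.714374
0.0762,0.489396,0.146486,0.0740114,0.709893
0.08,0.419003,0.145066,0.0687525,0.632822
0.09,0.287241,0.141506,0.0569631,0.48571
0.1,0.204562,0.138185,0.0476314,0.390378
0.125,0.0993291,0.130771,0.031717,0.261817
0.15,0.0549934,0.124403,0.0222582,0.201655
0.175,0.0334188,0.118864,0.016314,0.168597
0.2,0.0218004,0.113992,0.0123867,0.148179
0.25,0.0108339,0.105792,0.0077446,0.124371
0.3,0.00621016,0.0991203,0.00524447,0.110575
0.35,0.00392973,0.0935519,0.00376098,0.101243
0.4,0.00269095,0.0888085,0.00281544,0.0943149
0.45,0.00196379,0.0847001,0.0021789,0.0888428
0.5,0.00150199,0.0810928,0.00173153,0.0843263
0.55,0.00119324,0.0778889,0.00140602,0.0804882
0.6,0.00098967,0.075016,0.00116231,0.077168
0.7,0.000771235,0.0700534,0.000829236,0.0716539
0.8,0.000671466,0.0658913,0.000618726,0.0671815
0.9,0.000624213,0.0623287,0.000477784,0.0634307
1,0.000603639,0.0592304,0.0003791,0.0602131
1.1,0.000597748,0.056501,0.000307487,0.0574062
1.25,0.0006033,0.0529518,0.000232184,0.0537873
1.4,0.000616483,0.0499144,0.000180988,0.0507119
1.5,0.000626378,0.0481162,0.000155518,0.0488981
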