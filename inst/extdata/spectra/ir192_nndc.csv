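# Ir-192 photon emission spectrum, NNDC/ENSDF evaluation (transcribed;
# normalised to a total yield of 2.363 photons per decay above 10 keV).
# See inst/extdata/MANIFEST.md.
energy_MeV,photons_per_decay
0.0103553,0.00553006
0.0105109,0.00201093
0.0110707,0.013071
0.0112507,0.00422295
0.0120953,0.00100547
0.0129423,0.0030164
0.061486,0.0120656
0.063,0.020612
0.065122,0.0267454
0.066831,0.0457487
0.070821,0.00402186
0.071079,0.00784263
0.073363,0.00291585
0.075043,0.00894864
0.075749,0.0171935
0.07785,0.00623388
0.1104,0.000122667
0.136343,0.00200088
0.17698,4.3235e-05
0.201311,0.00475585
0.205794,0.0335825
0.28027,9.04919e-05
0.283267,0.00267454
0.295957,0.288669
0.308455,0.298623
0.316506,0.833128
0.32917,0.000174951
0.374485,0.00729968
0.416469,0.00672656
0.42052,0.000693771
0.468069,0.481015
0.484575,0.0320643
0.48906,0.00440394
0.588581,0.0454671
0.59349,0.000423301
0.604411,0.082609
0.612462,0.0536918
0.70385,5.32897e-05
0.7658,1.3071e-05
0.884537,0.00293093
1.06148,0.000533902
1.0899,1.20656e-05
1.3782,1.20656e-05
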