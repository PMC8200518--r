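# Photon mass attenuation coefficients for ir (cm^2/g), density 22.42 g/cm^3.
# mu_total is the exact sum of the three process columns.
# Physics-anchored construction; see inst/extdata/MANIFEST.md.
energy_MeV,mu_photoelectric,mu_incoherent,mu_coherent,mu_total
0.01,371.083,0.154507,0.741624,371.979
0.012,228.787,0.153381,0.737654,229.678
0.015,126.579,0.151731,0.730157,127.461
0.018,78.0411,0.150128,0.720837,78.9121
0.02,59.0126,0.149083,0.713646,59.8753
0.025,32.6495,0.146556,0.692483,33.4885
0.03,20.1297,0.14414,0.667309,20.9411
0.035,13.3737,0.141828,0.63893,14.1545
0.04,9.38467,0.139615,0.608219,10.1325
0.045,6.86641,0.137493,0.576045,7.57995
0.05,5.1922,0.135458,0.543208,5.87087
0.06,3.20119,0.131625,0.47819,3.811
0.07,2.12679,0.12808,0.417178,2.67205
0.076,1.70995,0.126077,0.383443,2.21947
0.0762,8.49037,0.126012,0.38236,8.99874
0.08,7.46214,0.12479,0.362296,7.94923
0.09,5.45976,0.121728,0.314256,5.89574
0.1,4.12853,0.118871,0.272904,4.5203
0.125,2.2879,0.112493,0.194497,2.59489
0.15,1.40827,0.107016,0.14244,1.65773
0.175,0.931461,0.102251,0.107337,1.14105
0.2,0.651073,0.0980599,0.0830403,0.832173
0.25,0.35998,0.0910057,0.0531078,0.504094
0.3,0.223855,0.0852664,0.036412,0.345533
0.35,0.151129,0.0804763,0.0263069,0.257912
0.4,0.108394,0.0763959,0.0197872,0.204577
0.45,0.0814187,0.0728617,0.0153629,0.169643
0.5,0.0634068,0.0697586,0.0122363,0.145402
0.55,0.0508268,0.0670025,0.00995245,0.127782
0.6,0.0417084,0.0645311,0.00823759,0.114477
0.7,0.0296783,0.0602622,0.00588697,0.0958275
0.8,0.0223556,0.0566818,0.00439722,0.0834346
0.9,0.017567,0.0536171,0.00339801,0.0745821
1,0.0142141,0.0509518,0.00269753,0.0678634
1.1,0.0117143,0.0486039,0.00218876,0.062507
1.25,0.00903756,0.0455508,0.00165337,0.0562417
1.4,0.00718074,0.0429379,0.00128915,0.0514078
1.5,0.00624255,0.0413911,0.00110787,0.0487415
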