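# Ir-192 photon emission spectrum, Duchemin & Coursol (1993) evaluation
# (approximate transcription).  See inst/extdata/MANIFEST.md.
energy_MeV,photons_per_decay
0.0104,0.011
0.011,0.016
0.0124,0.0055
0.061486,0.0128
0.063,0.0219
0.065122,0.0271
0.066831,0.0464
0.071,0.0154
0.0757,0.0261
0.136343,0.00183
0.201311,0.00459
0.205794,0.0331
0.283267,0.00269
0.295957,0.2872
0.308455,0.2968
0.316506,0.8271
0.374485,0.00727
0.416469,0.00671
0.468069,0.4781
0.484575,0.03175
0.48906,0.00428
0.588581,0.04498
0.604411,0.08231
0.612462,0.05313
0.884537,0.00288
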