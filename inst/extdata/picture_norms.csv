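picture,arousal_mean,arousal_sd,valence_mean,valence_sd
7234,3.41,2.29,4.01,1.32
5201,3.20,2.50,7.76,1.44
9290,4.75,2.20,2.71,1.35
1463,4.61,2.56,8.17,1.48
9181,6.20,2.23,1.84,1.25
8380,5.84,2.34,7.88,1.37
3102,6.92,2.50,1.29,0.79
4652,7.24,2.09,7.68,1.64
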