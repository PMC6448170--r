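# element=O Z=8 A=16 density_g_cm3=0.001332 version=1
energy_keV,mu_pe,mu_incoh,mu_coh,mu_total,mu_en
5,45.2998,0.196501,1.50368,46.999981,45.7
10,5.38322,0.192864,0.375921,5.952005,5.565
15,1.47953,0.189398,0.167076,1.836004,1.545
20,0.585026,0.186093,0.0939803,0.8650993,0.6179
30,0.156209,0.179922,0.041769,0.3779,0.1729
40,0.0607306,0.174274,0.0234951,0.2584997,0.0753
50,0.0290777,0.169085,0.0150368,0.2131995,0.04414
60,0.0159563,0.164301,0.0104423,0.1906996,0.03207
80,0.00615711,0.155769,0.00587377,0.16779988,0.02468
100,0.00296042,0.14838,0.00375921,0.15509963,0.02355
150,0.000847215,0.133582,0.00167076,0.136099975,0.02506
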