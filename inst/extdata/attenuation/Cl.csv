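# element=Cl Z=17 A=35.45 density_g_cm3=0.002995 version=1
energy_keV,mu_pe,mu_incoh,mu_coh,mu_total,mu_en
5,426.249,0.188436,3.56276,430.000196,410
10,56.4244,0.184948,0.890689,57.500037,55.5
15,17.2225,0.181625,0.395862,17.799987,17
20,7.33887,0.178455,0.222672,7.739997,7.26
30,2.1485,0.172537,0.0989655,2.4200025,2.1
40,0.911211,0.167121,0.0556681,1.1340001,0.885
50,0.467227,0.162146,0.0356276,0.6650006,0.452
60,0.274401,0.157558,0.0247414,0.4567004,0.2665
80,0.119707,0.149376,0.013917,0.283,0.1218
100,0.0634028,0.14229,0.00890689,0.21459969,0.0723
150,0.0206421,0.128099,0.00395862,0.15269972,0.0394
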