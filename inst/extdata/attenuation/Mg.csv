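# element=Mg Z=12 A=24.3 density_g_cm3=1.74 version=1
energy_keV,mu_pe,mu_incoh,mu_coh,mu_total,mu_en
5,136.391,0.194023,2.41521,139.000233,135
10,19.5058,0.190431,0.603802,20.300033,19.7
15,5.59463,0.18701,0.268357,6.049997,5.6
20,2.2753,0.183746,0.150951,2.609997,2.32
30,0.615258,0.177653,0.0670892,0.8600002,0.65
40,0.243186,0.172077,0.0377376,0.4530006,0.27
50,0.119895,0.166953,0.0241521,0.3110001,0.14
60,0.0675982,0.162229,0.0167723,0.2465995,0.0855
80,0.0277608,0.153805,0.00943441,0.19100021,0.045
100,0.0114528,0.146509,0.00603802,0.16399982,0.0329
150,0.00141896,0.131897,0.00268357,0.13599953,0.0266
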