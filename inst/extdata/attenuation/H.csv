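# element=H Z=1 A=1.008 density_g_cm3=8.375e-05 version=1
energy_keV,mu_pe,mu_incoh,mu_coh,mu_total,mu_en
5,0,0.389859,0.029441,0.4193,0.011
10,0,0.382642,0.00275816,0.38540016,0.00986
15,0,0.375767,0.000633483,0.376400483,0.01102
20,0,0.369209,0.000290529,0.369499529,0.01355
30,0,0.356966,3.39077e-05,0.3569999077,0.01863
40,0,0.345761,3.932e-05,0.34580032,0.02315
50,0,0.335466,3.39432e-05,0.3354999432,0.02709
60,0,0.325974,2.55233e-05,0.3259995233,0.03053
80,0,0.309046,5.36017e-05,0.3090996017,0.0362
100,0,0.294387,1.29129e-05,0.2943999129,0.04063
150,0,0.265027,7.28668e-05,0.2650998668,0.04813
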