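# element=Al Z=13 A=26.98 density_g_cm3=2.699 version=1
energy_keV,mu_pe,mu_incoh,mu_coh,mu_total,mu_en
5,190.616,0.189338,2.5945,193.399838,184
10,25.3955,0.185833,0.648624,26.229957,25.43
15,7.48423,0.182494,0.288277,7.955001,7.487
20,3.09953,0.179309,0.162156,3.440995,3.094
30,0.882568,0.173363,0.0720693,1.1280003,0.8778
40,0.36004,0.167921,0.040539,0.5685,0.3601
50,0.179234,0.162921,0.025945,0.3681,0.184
60,0.101471,0.158312,0.0180173,0.2778003,0.1099
80,0.0415747,0.150091,0.0101347,0.2018004,0.05511
100,0.0209426,0.142971,0.00648624,0.17039984,0.03794
150,0.00620492,0.128712,0.00288277,0.13779969,0.02827
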