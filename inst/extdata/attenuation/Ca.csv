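# element=Ca Z=20 A=40.08 density_g_cm3=1.55 version=1
energy_keV,mu_pe,mu_incoh,mu_coh,mu_total,mu_en
5,553.298,0.196107,4.50621,558.000317,540
10,92.091,0.192476,1.12655,93.410026,91
15,28.8103,0.189018,0.50069,29.500008,28.4
20,12.5926,0.185719,0.281638,13.059957,12.3
30,3.77527,0.179561,0.125173,4.080004,3.6
40,1.58567,0.173924,0.0704096,1.8300036,1.538
50,0.805192,0.168746,0.0450621,1.0190001,0.78
60,0.462535,0.163971,0.0312931,0.6577991,0.48
80,0.192541,0.155456,0.0176024,0.3655994,0.225
100,0.0977521,0.148082,0.0112655,0.2570996,0.138
150,0.0290794,0.133314,0.0050069,0.1674003,0.066
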