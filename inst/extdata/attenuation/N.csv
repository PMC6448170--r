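# element=N Z=7 A=14.01 density_g_cm3=0.001165 version=1
energy_keV,mu_pe,mu_incoh,mu_coh,mu_total,mu_en
5,29.6233,0.196391,1.28033,31.100021,29.9
10,3.36616,0.192755,0.320083,3.878998,3.545
15,0.904449,0.189292,0.142259,1.236,0.98
20,0.351791,0.185989,0.0800207,0.6178007,0.394
30,0.0912143,0.179821,0.0355647,0.3066,0.11
40,0.0346185,0.174176,0.0200052,0.2287997,0.0527
50,0.0162063,0.16899,0.0128033,0.1979996,0.0349
60,0.00859978,0.164209,0.00889119,0.18169997,0.0277
80,0.00321716,0.155682,0.00500129,0.16390045,0.0226
100,0.00140223,0.148297,0.00320083,0.15290006,0.0225
150,0.000370488,0.133507,0.00142259,0.135300078,0.0247
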