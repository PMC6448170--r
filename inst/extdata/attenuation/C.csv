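# element=C Z=6 A=12.01 density_g_cm3=1.7 version=1
energy_keV,mu_pe,mu_incoh,mu_coh,mu_total,mu_en
5,16.94,0.196309,1.06367,18.199979,17.7
10,1.91441,0.192675,0.265916,2.373001,2.078
15,0.499702,0.189213,0.118185,0.8071,0.5627
20,0.18961,0.185911,0.0664791,0.4420001,0.2238
30,0.0469076,0.179746,0.0295463,0.2561999,0.06614
40,0.0168764,0.174104,0.0166198,0.2076002,0.03343
50,0.00754329,0.16892,0.0106367,0.18709999,0.02397
60,0.00377276,0.164141,0.00738657,0.17530033,0.02098
80,0.00122832,0.155617,0.00415495,0.16100027,0.02037
100,0.000505625,0.148235,0.00265916,0.151399785,0.02147
150,6.68042e-05,0.133451,0.00118185,0.1346996542,0.02449
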