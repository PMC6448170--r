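# element=Ar Z=18 A=39.95 density_g_cm3=0.001662 version=1
energy_keV,mu_pe,mu_incoh,mu_coh,mu_total,mu_en
5,488.237,0.17707,3.58555,491.99962,470
10,60.9298,0.173792,0.896388,61.99998,60
15,18.9809,0.17067,0.398395,19.549965,18.7
20,8.23821,0.167691,0.224097,8.629998,8
30,2.43527,0.162131,0.0995987,2.6969997,2.33
40,1.03393,0.157041,0.0560243,1.2469953,0.993
50,0.541779,0.152365,0.0358555,0.7299995,0.51
60,0.319046,0.148054,0.0248997,0.4919997,0.3
80,0.144628,0.140366,0.0140061,0.2990001,0.136
100,0.0803283,0.133708,0.00896388,0.22300018,0.08
150,0.0306433,0.120373,0.00398395,0.15500025,0.0424
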