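# element=P Z=15 A=30.97 density_g_cm3=2.2 version=1
energy_keV,mu_pe,mu_incoh,mu_coh,mu_total,mu_en
5,296.713,0.19031,3.09639,299.9997,290
10,39.3091,0.186787,0.774097,40.269984,39
15,11.7725,0.183431,0.344043,12.299974,11.7
20,4.97625,0.18023,0.193524,5.350004,4.99
30,1.43974,0.174253,0.0860107,1.7000037,1.45
40,0.592835,0.168784,0.048381,0.81,0.61
50,0.297278,0.163758,0.0309639,0.4919999,0.312
60,0.168772,0.159125,0.0215027,0.3493997,0.1866
80,0.0694433,0.150861,0.0120953,0.2323996,0.0886
100,0.0350536,0.143705,0.00774097,0.18649957,0.0556
150,0.0103862,0.129373,0.00344043,0.14319963,0.0339
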