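energy,mu_over_rho,muen_over_rho,photoelectric_fraction
0.01,3.357,3.026,0.93803
0.015,1.101,0.9131,0.814444
0.02,0.5714,0.3586,0.648702
0.03,0.3032,0.1062,0.35991
0.04,0.235,0.05168,0.200072
0.05,0.2074,0.03433,0.120607
0.06,0.1924,0.02815,0.078868
0.08,0.1751,0.02541,0.040421
0.1,0.1641,0.02616,0.024666
0.15,0.1456,0.02883,0.010371
0.2,0.1328,0.031,0.005784
0.3,0.1152,0.03339,0.003419
0.4,0.1031,0.03431,0.002304
0.5,0.0941,0.03452,0.001852
0.6,0.08701,0.0344,0.001411
0.8,0.07641,0.03356,0.001196
1,0.0687,0.03247,0.001403
1.25,0.06143,0.03105,0.001604
1.5,0.05591,0.0297,0.003208
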