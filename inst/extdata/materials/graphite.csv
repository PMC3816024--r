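energy,mu_over_rho,muen_over_rho,photoelectric_fraction
0.01,2.373,2.078,0.918806
0.015,0.8071,0.5627,0.765566
0.02,0.442,0.2238,0.57939
0.03,0.2562,0.06614,0.29842
0.04,0.2076,0.03343,0.161356
0.05,0.1871,0.02397,0.097173
0.06,0.1753,0.02098,0.063665
0.08,0.161,0.02037,0.033443
0.1,0.1514,0.02147,0.02091
0.15,0.1347,0.02449,0.009277
0.2,0.1229,0.02655,0.005023
0.3,0.1066,0.0287,0.002543
0.4,0.09546,0.0295,0.002021
0.5,0.08715,0.02969,0.001833
0.6,0.08058,0.02956,0.001346
0.8,0.07076,0.02885,0.001085
1,0.06361,0.02792,0.001133
1.25,0.0569,0.02669,0.001709
1.5,0.05179,0.02551,0.003369
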