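energy,mu_over_rho,muen_over_rho,photoelectric_fraction
0.01,5.12,4.742,0.962395
0.015,1.614,1.334,0.882851
0.02,0.7779,0.5389,0.761179
0.03,0.3538,0.1537,0.492317
0.04,0.2485,0.06833,0.29988
0.05,0.208,0.04098,0.188463
0.06,0.1875,0.03041,0.125206
0.08,0.1662,0.02407,0.064344
0.1,0.1541,0.02325,0.038743
0.15,0.1356,0.02496,0.016546
0.2,0.1233,0.02672,0.00895
0.3,0.1067,0.02872,0.004181
0.4,0.09549,0.02949,0.003037
0.5,0.08712,0.02966,0.002193
0.6,0.08055,0.02953,0.001678
0.8,0.07074,0.02882,0.001507
1,0.06358,0.02789,0.001366
1.25,0.05687,0.02666,0.001886
1.5,0.05175,0.02547,0.003302
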