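energy,mu_over_rho,muen_over_rho,photoelectric_fraction
0.01,170.6,136.9,0.998947
0.015,57.08,48.96,0.996911
0.02,25.68,22.6,0.993253
0.03,8.176,7.251,0.97951
0.04,3.629,3.155,0.955287
0.05,1.958,1.638,0.919595
0.06,1.205,0.9555,0.873047
0.08,0.5952,0.4104,0.756327
0.1,0.3717,0.2177,0.628317
0.15,0.1964,0.07961,0.366721
0.2,0.146,0.04825,0.219399
0.3,0.1099,0.03361,0.098283
0.4,0.094,0.03039,0.055434
0.5,0.08414,0.02914,0.036426
0.6,0.07704,0.02836,0.026484
0.8,0.06699,0.02714,0.016615
1,0.05995,0.02603,0.012219
1.25,0.0535,0.02472,0.010461
1.5,0.04883,0.0236,0.014831
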