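energy,mu_over_rho,muen_over_rho,photoelectric_fraction
0.01,110,80,0.998595
0.015,115,85,0.998681
0.02,70,52,0.99787
0.03,25,19,0.994234
0.04,11.9,9.2,0.988268
0.05,6.7,5.2,0.979782
0.06,4.2,3.3,0.968661
0.076,2.2,1.8,0.942692
0.0762,9.5,4,0.986736
0.08,8.4,3.7,0.985144
0.1,4.86,2.4,0.975541
0.15,1.75,1,0.938848
0.2,0.866,0.52,0.886767
0.3,0.357,0.2,0.761158
0.4,0.212,0.105,0.639642
0.5,0.15,0.068,0.534943
0.6,0.118,0.051,0.453126
0.8,0.0857,0.037,0.338603
1,0.0695,0.0315,0.26688
1.25,0.058,0.0283,0.214641
1.5,0.0517,0.0268,0.199398
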