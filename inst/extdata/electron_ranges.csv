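material,energy,stopping_power,csda_range
graphite,0.001,110,4e-06
graphite,0.005,32,6.3e-05
graphite,0.01,19.7,3e-04
graphite,0.02,10.7,0.00102
graphite,0.05,5.79,0.00501
graphite,0.1,3.61,0.01625
graphite,0.2,2.45,0.0505
graphite,0.3,2.07,0.0951
graphite,0.5,1.79,0.1992
graphite,0.7,1.68,0.3146
graphite,1,1.63,0.4958
graphite,1.25,1.61,0.65
graphite,1.5,1.6,0.805
air,0.001,107.8,4e-06
air,0.005,31.36,6.4e-05
air,0.01,19.306,0.000306
air,0.02,10.486,0.00104
air,0.05,5.6742,0.00511
air,0.1,3.5378,0.016575
air,0.2,2.401,0.05151
air,0.3,2.0286,0.097002
air,0.5,1.7542,0.203184
air,0.7,1.6464,0.320892
air,1,1.5974,0.505716
air,1.25,1.5778,0.663
air,1.5,1.568,0.8211
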