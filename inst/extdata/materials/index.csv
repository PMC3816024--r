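name,density,z_over_a
graphite,1.7,0.499542086420781
air,0.00120479,0.49919
pmma,1.19,0.53936893834214
steel316,8.02,0.46557435759692
iridium,22.42,0.400588917733603
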