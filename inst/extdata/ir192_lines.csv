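energy,intensity
0.06149,0.012
0.063,0.0205
0.06512,0.0263
0.06683,0.0449
0.0716,0.0085
0.0756,0.0155
0.0779,0.0042
0.136343,0.00199
0.201311,0.00473
0.205794,0.0334
0.283267,0.00269
0.295957,0.2872
0.308455,0.2968
0.316506,0.8286
0.374485,0.00726
0.416469,0.0067
0.468069,0.4781
0.484575,0.03189
0.48906,0.00438
0.588581,0.04517
0.604411,0.082
0.612462,0.0534
0.884537,0.00292
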