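p,delta_qaly,delta_cost
0.03,0.001,1940
0.50,0.0728,1630
0.92,0.1492,1171
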