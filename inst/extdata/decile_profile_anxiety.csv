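decile,mean_theta,n_simulees
D2,-1.42,39
D3,-0.81,20
D4,-0.50,19
D5,-0.18,20
D6,0.15,20
D7,0.34,19
D8,0.54,19
D9,0.89,20
D10,1.48,20
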