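decile,mean_theta,n_simulees
D2,-1.45,40
D3,-0.73,20
D4,-0.45,20
D5,-0.24,19
D6,0.14,20
D7,0.39,20
D8,0.68,18
D9,0.93,22
D10,1.47,20
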