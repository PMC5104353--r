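lower_hours,upper_hours,probability
1,5,0.65
6,10,0.22
11,15,0.13
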