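count,probability
1,0.05
2,0.10
3,0.85
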