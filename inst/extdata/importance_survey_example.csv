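rater,median overall survival,annual direct medical costs,budget impact,equity
r1,5,4,3,3
r2,5,5,4,3
r3,4,4,3,2
r4,5,4,3,4
r5,4,5,4,3
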