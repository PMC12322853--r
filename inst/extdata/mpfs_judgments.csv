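,L1,L2,L3,L4,L5
L1,,weak,moderate,very strong,extreme
L2,,,weak,moderate,very strong
L3,,,,weak,moderate
L4,,,,,weak
L5,,,,,
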