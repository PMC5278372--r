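component,percent
N,36.45
H,30.62
M,26.97
F,5.95
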