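source,F,G,H
m1,1,0,0
m2,0,1,0
m3,0.8,0.1,0.1
m4,0.8,0.1,0.1
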