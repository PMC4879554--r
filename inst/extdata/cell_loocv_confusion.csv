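true,PS1 P,PS1 R,PS2 P,PS2 R,SF268 P,SF268 R,U87MG P,U87MG R
PS1 P,17,0,0,0,0,0,0,0
PS1 R,0,16,0,0,0,0,0,0
PS2 P,0,0,16,0,0,0,0,0
PS2 R,1,0,0,14,0,1,0,0
SF268 P,0,0,0,0,20,0,0,0
SF268 R,0,0,0,1,0,18,0,0
U87MG P,0,0,0,0,0,0,18,0
U87MG R,0,0,0,5,0,1,1,15
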