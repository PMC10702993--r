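# toy follower edge list: 6 users, comma or whitespace separated
u1 u2
u1,u3
u2 u3
u3 u4
u4 u5
u5 u6
u6 u4
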