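pattern,count
000,1910
010,1814
011,4341
100,210
110,267
111,769
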