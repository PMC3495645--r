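1st
2nd
3rd
4th
5th
first
second
third
fourth
fifth
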