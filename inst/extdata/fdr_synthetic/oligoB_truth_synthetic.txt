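# SYNTHETIC truth annotation (stand-in, not original data)
[3,3,1,8,0]
[3,3,1,9,0]
[3,3,1,10,0]
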