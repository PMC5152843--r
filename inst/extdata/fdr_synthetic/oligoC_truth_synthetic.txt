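# SYNTHETIC truth annotation (stand-in, not original data)
[2,2,1,4,0]
[2,2,1,5,0]
[2,2,1,3,0]
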