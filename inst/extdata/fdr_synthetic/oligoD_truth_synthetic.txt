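# SYNTHETIC truth annotation (stand-in, not original data)
[4,4,1,10,0]
[4,4,1,11,0]
[4,4,1,12,0]
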