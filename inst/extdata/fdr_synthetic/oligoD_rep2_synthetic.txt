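Compound Key	Score	Total Volume
[4,1,1,10,1] 6NH3	0.0007	2956.35
[1,3,1,11,2] 4NH3	0.0254	3092.99
[1,3,1,7,2] 4NH3	0.1436	2055.59
[3,1,1,6,2] 5NH3	0.5599	2761.42
[5,3,1,9,0] 4NH3	0.3204	5162.32
[4,4,1,10,0] 1NH3	0.1374	2296.48
[4,4,1,12,0] 4NH3	0.9540	15678.18
[4,4,1,11,0] 1NH3	0.7397	1608.76
[1,3,1,8,2] 3NH3	0.0490	26161.63
[2,6,1,11,1] 2NH3	0.8785	18546.26
[4,4,1,8,1] 5NH3	0.4758	1284.44
[3,5,1,10,1] 1NH3	0.8908	8851.61
[1,1,1,1,2] 2NH3	0.8491	7219.06
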