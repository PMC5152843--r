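Compound Key	Score	Total Volume
[3,1,1,4,1] 4NH3	0.9946	1685.24
[1,3,1,5,0] 3NH3	0.5509	13112.04
[5,5,1,4,0] 3NH3	0.9873	38481.78
[2,4,1,4,0] 6NH3	0.2120	8203.87
[5,2,1,1,2] 3NH3	0.1073	15447.98
[2,1,1,7,2] 5NH3	0.9480	19285.66
[6,1,1,0,0] 6NH3	0.6314	10451.51
[2,2,1,3,0] 4NH3	0.9956	1188.34
[4,2,1,10,2] 5NH3	0.4673	1167.15
[6,3,1,3,0] 5NH3	0.7848	20272.21
[2,3,1,6,0] 4NH3	0.9539	30171.71
[5,2,1,1,0] 3NH3	0.8157	13274.00
[2,2,1,5,0] 3NH3	0.4530	2016.79
[1,6,1,6,2] 2NH3	0.3275	2238.12
[2,2,1,4,0] 5NH3	0.7491	3882.42
[2,4,1,4,2] 5NH3	0.4653	4039.31
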