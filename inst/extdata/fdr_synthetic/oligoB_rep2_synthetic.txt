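Compound Key	Score	Total Volume
[1,3,1,2,0] 1NH3	0.9963	6847.75
[3,3,1,10,0] 5NH3	0.4363	20311.76
[4,3,1,9,0] 5NH3	0.3506	15545.96
[3,3,1,9,0] 3NH3	0.9372	10291.78
[4,4,1,11,0] 2NH3	0.5131	5207.96
[2,1,1,12,1] 6NH3	0.1383	31689.29
[5,4,1,9,0] 4NH3	0.0876	11305.81
[3,3,1,8,0]	0.4883	23874.17
[4,5,1,7,2] 5NH3	0.3757	5194.11
[2,2,1,5,0] 4NH3	0.0731	97706.22
[2,3,1,11,0] 4NH3	0.5544	6031.17
[4,4,1,10,0] 5NH3	0.3688	29138.97
[6,6,1,8,0] 2NH3	0.9750	34353.06
[4,2,1,10,1] 1NH3	0.0192	8097.63
[5,2,1,9,1] 5NH3	0.9159	17518.97
[1,6,1,6,0]	0.9672	6460.40
[4,3,1,10,2] 1NH3	0.5125	25072.51
[2,6,1,12,2] 4NH3	0.7502	7154.31
[3,3,1,1,1] 4NH3	0.3147	8388.09
[3,4,1,8,1] 1NH3	0.4033	73128.23
[2,3,1,7,1] 5NH3	0.6828	17565.57
[2,4,1,0,2] 6NH3	0.2212	9952.24
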