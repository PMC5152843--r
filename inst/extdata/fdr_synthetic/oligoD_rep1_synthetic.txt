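Compound Key	Score	Total Volume
[4,3,1,11,1] 2NH3	0.7883	27106.01
[3,4,1,2,0] 3NH3	0.9421	18194.06
[3,3,1,2,2] 4NH3	0.8701	24703.94
[5,3,1,9,0] 4NH3	0.1900	4459.41
[4,3,1,0,0] 3NH3	0.7014	33078.31
[4,4,1,12,0] 1NH3	0.1549	35443.92
[5,3,1,8,2] 3NH3	0.9724	19529.94
[1,1,1,10,2] 4NH3	0.0538	15738.36
[4,4,1,11,0] 2NH3	0.9405	7196.86
[3,5,1,10,1] 4NH3	0.6083	24921.86
[2,2,1,3,0] 6NH3	0.4281	8232.29
[4,2,1,5,0] 4NH3	0.4601	23033.76
[4,5,1,9,2] 3NH3	0.6673	30860.46
[4,4,1,10,0] 4NH3	0.2290	20361.92
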