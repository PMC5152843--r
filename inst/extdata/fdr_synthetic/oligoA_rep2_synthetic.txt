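Compound Key	Score	Total Volume
[1,6,1,8,1] 4NH3	0.4647	8487.68
[3,3,1,7,0] 3NH3	0.7474	19838.34
[3,5,1,6,0] 5NH3	0.4635	24036.85
[3,3,1,6,0] 5NH3	0.5886	25610.77
[3,2,1,7,1] 4NH3	0.2717	4543.44
[2,4,1,6,1] 2NH3	0.6335	3446.79
[1,3,1,5,1] 4NH3	0.4065	5556.80
[4,1,1,4,2] 2NH3	0.0826	8571.10
[4,4,1,7,2] 2NH3	0.1131	28360.75
[2,6,1,2,2] 5NH3	0.6525	29549.46
[6,5,1,4,2] 3NH3	0.6720	56804.93
[6,2,1,1,0] 4NH3	0.4042	11472.49
[4,2,1,8,0] 5NH3	0.4022	7530.62
[3,4,1,1,2] 2NH3	0.7157	12752.60
[6,5,1,3,1] 6NH3	0.8717	11600.61
[3,3,1,5,0] 4NH3	0.4003	28399.93
[1,3,1,1,0] 3NH3	0.2354	6808.33
[6,5,1,5,2] 4NH3	0.1637	29526.66
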