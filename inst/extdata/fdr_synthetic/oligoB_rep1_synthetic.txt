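Compound Key	Score	Total Volume
[3,4,1,5,0]	0.2204	19661.96
[5,3,1,0,0] 4NH3	0.5381	8434.79
[2,3,1,7,1] 1NH3	0.6694	14802.18
[1,4,1,8,2] 5NH3	0.9068	6665.25
[4,3,1,9,0] 3NH3	0.5596	2237.68
[6,4,1,5,2]	0.2370	1392.04
[2,2,1,5,0]	0.3713	8537.28
[4,4,1,11,0] 4NH3	0.9999	24695.23
[4,6,1,3,1] 2NH3	0.2617	12432.18
[5,6,1,5,2] 4NH3	0.7279	6026.20
[3,6,1,1,0] 1NH3	0.1361	4247.44
[2,6,1,3,1] 2NH3	0.9229	83931.12
[3,4,1,8,1]	0.9883	9751.78
[1,1,1,10,2] 2NH3	0.1973	7281.09
[1,6,1,0,0] 3NH3	0.6746	11641.26
[3,3,1,10,0] 3NH3	0.2082	78995.81
[3,3,1,9,0] 3NH3	0.6942	23822.98
[3,3,1,8,0] 4NH3	0.6034	11166.56
[3,1,1,8,2] 3NH3	0.1513	57879.37
[5,3,1,9,2] 1NH3	0.0779	1828.81
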