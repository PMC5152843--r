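Compound Key	Score	Total Volume
[4,2,1,8,0] 2NH3	0.7129	4006.06
[3,3,1,7,0] 1NH3	0.3216	34118.45
[1,4,1,5,1] 4NH3	0.2423	15249.66
[4,2,1,8,0] 4NH3	0.1860	20321.88
[3,3,1,7,0] 5NH3	0.4698	7912.57
[2,4,1,6,1] 6NH3	0.5678	5977.59
[6,5,1,9,2]	0.4162	38081.10
[4,4,1,5,0] 5NH3	0.6278	982.34
[3,3,1,12,1] 3NH3	0.4262	5028.54
[6,1,1,5,0] 5NH3	0.3479	1429.13
[2,5,1,1,1] 5NH3	0.0635	3597.59
[3,3,1,6,0] 3NH3	0.2139	1614.61
[3,3,1,6,0] 4NH3	0.5470	5237.36
[3,3,1,5,0] 1NH3	0.4580	5368.21
[5,4,1,4,1] 5NH3	0.7901	15789.41
[3,3,1,5,0] 4NH3	0.9841	5763.91
[4,3,1,7,1] 2NH3	0.4569	20622.79
[1,6,1,1,2] 5NH3	0.1679	10191.08
[5,2,1,9,0] 1NH3	0.4433	2336.93
[4,4,1,1,0] 4NH3	0.6316	6899.87
[3,1,1,8,1] 6NH3	0.8434	473.40
[2,4,1,6,1] 5NH3	0.3830	7791.41
[6,6,1,6,2] 1NH3	0.1607	10746.79
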