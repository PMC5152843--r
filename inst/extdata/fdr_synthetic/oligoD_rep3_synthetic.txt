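Compound Key	Score	Total Volume
[4,6,1,0,1] 2NH3	0.7404	5223.03
[6,6,1,10,0]	0.8887	5265.03
[4,5,1,6,2]	0.3297	15017.12
[5,6,1,10,1] 2NH3	0.9244	4191.08
[4,4,1,12,0] 3NH3	0.1278	35701.06
[2,6,1,7,1] 3NH3	0.6075	18392.23
[6,6,1,12,1] 2NH3	0.5681	2116.07
[6,4,1,3,0] 5NH3	0.2843	5648.41
[4,4,1,11,0]	0.9832	7466.68
[3,2,1,6,0] 6NH3	0.5007	14164.08
[3,5,1,10,1] 6NH3	0.0638	12471.33
[4,4,1,10,0] 3NH3	0.3764	17314.18
[6,2,1,4,1] 2NH3	0.1637	70263.59
[5,3,1,9,0] 4NH3	0.1602	14600.26
[2,3,1,7,0]	0.2443	5113.21
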