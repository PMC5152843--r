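Compound Key	Score	Total Volume
[1,4,1,12,1] 3NH3	0.9689	2191.55
[5,1,1,4,1] 5NH3	0.9370	10635.34
[2,2,1,4,0]	0.2718	4402.34
[6,6,1,3,1] 2NH3	0.6242	3647.02
[2,4,1,6,1] 6NH3	0.6505	106780.68
[3,3,1,3,0] 5NH3	0.5597	40720.06
[2,6,1,3,0]	0.5035	3708.78
[2,3,1,6,0] 3NH3	0.5404	6092.43
[3,1,1,4,1] 2NH3	0.3297	39361.85
[2,2,1,3,0]	0.1090	4264.60
[1,3,1,5,0] 6NH3	0.2370	122207.83
[2,3,1,3,2]	0.4640	40885.77
[2,2,1,5,0] 3NH3	0.1486	14251.10
[3,2,1,12,1] 6NH3	0.8118	4848.12
[3,5,1,2,0] 3NH3	0.5121	7203.34
[4,4,1,2,0] 2NH3	0.8422	4053.93
[1,4,1,3,2] 3NH3	0.4189	182932.61
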