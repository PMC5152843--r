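Compound Key	Score	Total Volume
[6,5,1,2,1] 3NH3	0.2502	5403.81
[3,3,1,5,0] 1NH3	0.5372	2622.37
[1,6,1,12,0] 1NH3	0.5920	18414.48
[2,6,1,4,0] 4NH3	0.3993	55691.62
[3,3,1,11,2] 1NH3	0.9513	6373.51
[6,5,1,6,1] 3NH3	0.4954	9248.34
[3,3,1,7,0] 2NH3	0.9661	6916.79
[2,6,1,4,1] 3NH3	0.5054	12086.79
[3,3,1,6,0] 6NH3	0.6712	6605.56
[3,1,1,9,1] 5NH3	0.7640	42939.77
[5,2,1,3,0] 1NH3	0.1958	3692.76
[4,2,1,8,0] 4NH3	0.2638	9881.44
[3,1,1,0,0] 3NH3	0.2971	2510.41
[2,4,1,6,1] 1NH3	0.3422	3799.60
[5,4,1,4,0] 4NH3	0.2371	5677.08
[4,5,1,10,2] 3NH3	0.4808	7086.41
[5,2,1,8,0] 3NH3	0.9708	6762.19
[3,1,1,0,2] 3NH3	0.0567	5225.03
[3,4,1,7,0] 3NH3	0.1758	2124.07
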