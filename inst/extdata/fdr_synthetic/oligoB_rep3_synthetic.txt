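Compound Key	Score	Total Volume
[2,3,1,7,1] 6NH3	0.6069	3393.07
[4,3,1,9,0] 1NH3	0.3814	49823.61
[3,3,1,9,0] 3NH3	0.0232	41605.89
[6,2,1,6,1] 3NH3	0.1589	8983.27
[3,3,1,10,0] 4NH3	0.6934	2742.60
[6,3,1,2,0] 2NH3	0.8528	12373.69
[3,3,1,8,0] 1NH3	0.0816	37066.19
[6,3,1,5,2] 3NH3	0.9435	11227.92
[4,4,1,12,2]	0.8171	1768.86
[2,6,1,7,2] 4NH3	0.7970	12836.84
[5,5,1,7,0] 2NH3	0.3294	9487.46
[5,4,1,2,1] 1NH3	0.8485	8786.09
[1,4,1,7,2] 5NH3	0.9878	13017.07
[4,4,1,11,0] 4NH3	0.0164	7391.63
[6,1,1,4,2] 2NH3	0.3112	3320.45
[3,4,1,8,1] 5NH3	0.7265	61881.33
[3,2,1,9,0] 5NH3	0.6019	4701.18
[5,4,1,6,0] 6NH3	0.6159	10919.69
[2,2,1,5,0] 3NH3	0.2789	50980.51
[6,2,1,12,1] 1NH3	0.1456	9523.03
[6,1,1,0,2]	0.6984	151401.01
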