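Compound Key	Score	Total Volume
[6,3,1,12,0] 6NH3	0.2584	4760.00
[3,2,1,8,2] 5NH3	0.2451	25718.69
[2,1,1,6,0] 4NH3	0.7329	17458.98
[2,3,1,6,0]	0.7195	7372.20
[3,1,1,4,1] 1NH3	0.4176	13545.64
[2,2,1,5,0] 6NH3	0.0090	15591.25
[4,1,1,5,0]	0.4646	3992.49
[4,6,1,12,1] 3NH3	0.8820	8214.51
[6,6,1,2,1] 4NH3	0.0622	4249.32
[2,2,1,4,0] 1NH3	0.9038	67840.34
[2,6,1,10,2] 3NH3	0.3539	15724.52
[1,3,1,5,0] 3NH3	0.7269	6187.51
[2,2,1,3,0] 4NH3	0.9047	25588.02
[4,6,1,4,0] 4NH3	0.7323	3195.29
[6,4,1,1,1] 6NH3	0.1636	32721.97
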