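element	sigma_A	epsilon_kcal
C	3.55	0.07
N	3.25	0.17
O	2.96	0.21
S	3.55	0.25
P	3.74	0.2
F	2.94	0.061
CL	3.4	0.3
BR	3.54	0.4
I	3.77	0.5
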