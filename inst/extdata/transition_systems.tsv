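system	reference	level	energy_hartree	mux	muy	muz
two_level	ground	1	0.5	0	0	1.0
three_level_excited	excited	1	-0.15	0.4	0	0.6
three_level_excited	excited	2	0.45	0.3	0.3	0
five_level	ground	1	0.3	0.2	0	0.5
five_level	ground	2	0.5	0	0.4	0.3
five_level	ground	3	0.8	0.3	0.3	0.1
five_level	ground	4	1.2	0.1	0.2	0.2
hydrogen_like	ground	1	0.375	0	0	1.55
hydrogen_like	ground	2	1.0	0	0	0.55
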