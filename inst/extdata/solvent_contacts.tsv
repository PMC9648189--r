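name	contact_on_O	contact_elsewhere
water	1.86	2.96
ethanol	1.86	3.932
cyclohexane	5.20	5.20
chloroform	4.82	4.82
carbon tetrachloride	5.20	5.20
toluene	5.01	5.01
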