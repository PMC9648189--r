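name	eta0	A2	A4	ionization_hartree	first_absorption_eV
water	1.32315	0.00201432	6.21176e-06	0.4638	NA
ethanol	1.35059	0.00226353	7.02316e-06	0.385133	NA
cyclohexane	1.41142	0.00259217	1.25986e-05	0.3631	7.44
chloroform	1.43108	0.00260712	3.60209e-05	0.41784	NA
carbon tetrachloride	1.44277	0.00332168	1.48334e-05	0.4215	NA
toluene	1.48437	0.0016524	0.000241204	0.3245	NA
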