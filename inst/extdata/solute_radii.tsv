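element	radius_bohr
C	3.26
O	2.81
H	2.33
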