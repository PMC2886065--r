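x	y	z	family	rho_max	kappa	expected_la
g0001	g0002	g0003	tanh	0.9	4	0.701432278597472
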