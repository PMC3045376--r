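roi	FP	pSTS	PCC	rACC
FP	1	3.7200000000000002	3.5153999999999996	0
pSTS	3.7200000000000002	32.3108	29.693525999999995	-4.1799999999999997
PCC	3.5153999999999996	29.693525999999995	28.306812969999992	-3.7490999999999994
rACC	0	-4.1799999999999997	-3.7490999999999994	1
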