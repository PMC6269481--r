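sample_id	os_time	os_event	mycn_amplified	stage4	age_ge_1y
sample_001	9.3	0	1	1	1
sample_002	5.09	1		0	1
sample_003	1.14	1	0	1	0
sample_004	9.08	0	0	0	1
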