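feature_id	sample_001	sample_002	sample_003	sample_004
sim-mir-up-001	0.716	-0.606	2.756	-0.61
sim-mir-up-002	1.732	-0.736	1.814	-0.963
sim-mir-down-001	-4.052	-0.042	-1.871	1.091
sim-mir-down-002	-2.032	1.909	-1.396	-0.139
sim-mir-bg-001	-0.462	-1.521	0.237	-0.596
sim-mir-bg-002	-0.556	-0.437	-0.144	-1.147
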