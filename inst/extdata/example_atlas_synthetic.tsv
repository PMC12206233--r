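roi_id	x	y	z	network
SMN_001	-66	-90	-60	SMN
SMN_002	-54	-90	-60	SMN
SMN_003	-42	-90	-60	SMN
SMN_004	-66	-78	-60	SMN
SMN_005	-54	-78	-60	SMN
DMN_001	-42	-78	-60	DMN
DMN_002	-66	-66	-60	DMN
DMN_003	-54	-66	-60	DMN
DMN_004	-42	-66	-60	DMN
DMN_005	-66	-90	-48	DMN
DMN_006	-54	-90	-48	DMN
FPN_001	-42	-90	-48	FPN
FPN_002	-66	-78	-48	FPN
FPN_003	-54	-78	-48	FPN
FPN_004	-42	-78	-48	FPN
ATN_001	-66	-66	-48	ATN
ATN_002	-54	-66	-48	ATN
ATN_003	-42	-66	-48	ATN
none_001	-66	-90	-36	none
none_002	-54	-90	-36	none
none_003	-42	-90	-36	none
none_004	-66	-78	-36	none
none_005	-54	-78	-36	none
none_006	-42	-78	-36	none
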