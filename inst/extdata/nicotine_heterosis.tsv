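year	stage	mph	oph	bph
2013	BT	11.48	3.92	20.24
2013	AT	34.56	24.65	46.18
2014	BT	10.39	2.13	20.11
2014	AT	40.84	28.38	55.99
2015	BT	2.83	2.36	3.31
2015	AT	44.82	33.48	58.26
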