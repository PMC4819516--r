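marker	position	ancestral	derived	haplogroup	parent
M130	100	A	G	C-M130	
M347	200	C	T	C-M347	C-M130
M210	300	G	A	C-M210	C-M130
M526	400	T	C	K-M526	
P308	500	A	T	S-P308	K-M526
M186	600	G	C	M-M186	K-M526
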