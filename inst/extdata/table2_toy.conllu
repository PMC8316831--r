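# sent_id = s1
1	Ta	_	r	_	_	2	SBV	_	_
2	Kan	_	v	_	_	0	HED	_	_
3	Shu	_	n	_	_	2	VOB	_	_

# sent_id = s2
1	Ta	_	r	_	_	4	SBV	_	_
2	Zai	_	p	_	_	4	ADV	_	_
3	Xuexiao	_	n	_	_	2	POB	_	_
4	Kan	_	v	_	_	0	HED	_	_
5	Shu	_	n	_	_	4	VOB	_	_
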