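# toy two-sentence annotation: "Ta Kan Shu" / "Ta Zai Xuexiao Kan Shu"
# columns: sentence_id, order, form, pos, governor_order, governor_form, relation
s1	1	Ta	r	2	Kan	SBV
s1	2	Kan	v	0	_	HED
s1	3	Shu	n	2	Kan	VOB
s2	1	Ta	r	4	Kan	SBV
s2	2	Zai	p	4	Kan	ADV
s2	3	Xuexiao	n	2	Zai	POB
s2	4	Kan	v	0	_	HED
s2	5	Shu	n	4	Kan	VOB
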