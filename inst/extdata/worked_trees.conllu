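# sent_id = wx.rule1_conjunction
1	PROTEIN0	protein0	PROPN	_	_	3	nsubj	_	_
2	directly	directly	ADV	_	_	3	advmod	_	_
3	interacts	interacts	VERB	_	_	0	root	_	_
4	with	with	ADP	_	_	5	case	_	_
5	PROTEIN1	protein1	PROPN	_	_	3	prep_with	_	_
6	and	and	CCONJ	_	_	5	cc	_	_
7	PROTEIN2	protein2	PROPN	_	_	5	conj_and	_	_

# sent_id = wx.rule2_binding_of_to
1	binding	binding	NOUN	_	_	0	root	_	_
2	of	of	ADP	_	_	3	case	_	_
3	PROTEIN0	protein0	PROPN	_	_	1	prep_of	_	_
4	to	to	ADP	_	_	5	case	_	_
5	PROTEIN1	protein1	PROPN	_	_	1	prep_to	_	_

# sent_id = wx.rule3_between
1	the	the	DET	_	_	2	det	_	_
2	interaction	interaction	NOUN	_	_	0	root	_	_
3	between	between	ADP	_	_	4	case	_	_
4	PROTEIN0	protein0	PROPN	_	_	2	prep_between	_	_
5	and	and	CCONJ	_	_	4	cc	_	_
6	PROTEIN1	protein1	PROPN	_	_	4	conj_and	_	_

# sent_id = wx.rule4_plain
1	PROTEIN0	protein0	PROPN	_	_	4	nsubj	_	_
2	and	and	CCONJ	_	_	1	cc	_	_
3	PROTEIN1	protein1	PROPN	_	_	1	conj_and	_	_
4	interact	interact	VERB	_	_	0	root	_	_

# sent_id = wx.rule5_negated
1	no	no	DET	_	_	5	det	_	_
2	PROTEIN0	protein0	PROPN	_	_	5	nn	_	_
3	-	-	PUNCT	_	_	5	punct	_	_
4	PROTEIN1	protein1	PROPN	_	_	5	nn	_	_
5	complex	complex	NOUN	_	_	7	nsubjpass	_	_
6	was	was	AUX	_	_	7	auxpass	_	_
7	detected	detected	VERB	_	_	0	root	_	_

# sent_id = wx.rule6_receptor_for
1	PROTEIN0	protein0	PROPN	_	_	4	nsubj	_	_
2	is	is	AUX	_	_	4	cop	_	_
3	a	a	DET	_	_	4	det	_	_
4	receptor	receptor	NOUN	_	_	0	root	_	_
5	for	for	ADP	_	_	6	case	_	_
6	PROTEIN1	protein1	PROPN	_	_	4	prep_for	_	_

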