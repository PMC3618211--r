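mipr	pos_relations	neg_relations	pos_instances	neg_instances	rel_tp	rel_fp	inst_tp	inst_fp
1	618	2312	1000	4834	132	7	153	10
2	197	695	579	2827	80	3	101	5
3	89	314	363	1835	51	2	67	3
4	51	181	249	1349	35	2	50	3
5	28	107	157	984	23	1	37	1
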