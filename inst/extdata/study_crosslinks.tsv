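chain_a	res_a	kind_a	chain_b	res_b	kind_b	n_bs2g	n_bs3	n_pdh	total	best_evalue	ca_dist_ref	remark
CyclinT1	6	lysine	CDK9	144	lysine	13	15	0	28	1.7e-10	18.5	
CyclinT1	6	lysine	CDK9	74	lysine	9	35	0	44	3.7e-11	11.2	
CyclinT1	100	lysine	CDK9	56	lysine	30	25	0	55	2.5e-13	9.3	
EIN	1	n_terminus	HPr	24	lysine	26	0	0	26	2.4e-18	49.1	EC-III
EIN	1	n_terminus	HPr	49	lysine	23	14	0	37	1.3e-32	45.0	EC-III
EIN	29	lysine	HPr	1	n_terminus	0	18	0	18	9.4e-16	49.1	EC-II
EIN	30	lysine	HPr	1	n_terminus	0	7	0	7	1.1e-18	46.9	EC-II
EIN	30	lysine	HPr	24	lysine	25	74	0	99	2.1e-24	36.8	EC-II
EIN	30	lysine	HPr	27	lysine	31	12	0	43	1.2e-23	35.3	EC-II
EIN	30	lysine	HPr	49	lysine	3	1	0	4	7.8e-42	29.9	EC-II
EIN	30	lysine	HPr	79	lysine	0	10	0	10	2.2e-10	49.5	EC-II
EIN	49	lysine	HPr	24	lysine	15	0	0	15	8.4e-21	22.3	EC-I
EIN	49	lysine	HPr	49	lysine	0	36	0	36	2.0e-25	26.5	EC-I
EIN	49	lysine	HPr	72	lysine	8	0	0	8	1.3e-18	35.2	EC-I
EIN	58	lysine	HPr	24	lysine	1	13	0	14	2.5e-26	15.4	SC
EIN	238	lysine	HPr	24	lysine	9	0	0	9	2.5e-18	56.1	EC-III
Ub	6	lysine	Ub	48	lysine	24	24	0	48	5.1e-17		
Ub	6	lysine	Ub	63	lysine	23	2	0	25	4.5e-17		
Ub	11	lysine	Ub	48	lysine	3	83	0	86	1.6e-24		
Ub	29	lysine	Ub	48	lysine	15	22	0	37	1.8e-12		
Ub	33	lysine	Ub	48	lysine	17	78	0	95	7.5e-24		
Ub	48	lysine	Ub	48	lysine	67	103	0	170	3.5e-18		
Ub	63	lysine	Ub	63	lysine	8	0	0	8	3.3e-19		
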