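primer	sequence	TNB	NPB	PPB	H	PIC	MI	Rp	GI
SCoT4	caacaatggctaccacct	12	9	75.00	0.524	0.347	3.121	4.703	0.784
SCoT5	caacaatggctaccacga	6	6	100.00	0.518	0.340	2.039	2.811	0.459
SCoT7	caacaatggctaccacgg	10	10	100.00	0.564	0.385	3.845	5.892	0.838
SCoT8	caacaatggctaccacgt	9	7	77.78	0.459	0.294	2.060	2.919	0.486
SCoT10	caacaatggctaccagcc	14	11	78.57	0.520	0.343	3.778	5.243	0.811
SCoT21	acgacatggcgacccaca	24	19	79.17	0.564	0.385	7.322	11.405	1.000
SCoT23	caccatggctaccaccag	17	11	64.71	0.558	0.376	4.131	6.000	0.892
SCoT25	accatggctaccaccggg	20	18	90.00	0.514	0.340	6.124	8.919	1.000
SCoT31	ccatggctaccaccgcct	10	8	80.00	0.477	0.310	2.478	3.351	0.541
SCoT32	ccatggctaccaccgcac	12	8	66.67	0.570	0.390	3.118	5.135	0.757
SCoT33	ccatggctaccaccgcag	13	9	69.23	0.551	0.374	3.369	5.189	0.757
SCoT43	caatggctaccaccgcag	20	17	85.00	0.517	0.346	5.876	9.081	1.000
SCoT46	acaatggctaccactgag	11	7	63.64	0.617	0.429	3.001	4.865	0.649
SCoT47	acaatggctaccactgcc	15	8	53.33	0.593	0.408	3.261	5.297	0.730
SCoT48	acaatggctaccactggc	11	8	72.73	0.520	0.346	2.770	4.270	0.622
SCoT52	acaatggctaccactgca	20	16	80.00	0.519	0.346	5.537	8.649	0.946
SCoT55	acaatggctaccactacc	15	12	80.00	0.532	0.356	4.275	6.216	1.000
SCoT57	acaatggctaccactacg	10	7	70.00	0.543	0.368	2.577	4.108	0.568
SCoT59	acaatggctaccaccatc	14	10	71.43	0.519	0.349	3.495	5.622	0.838
SCoT60	acaatggctaccaccaca	17	9	52.94	0.570	0.386	3.471	5.297	0.757
SCoT83	acgacatggcgaccagcg	17	12	70.59	0.424	0.267	3.205	4.378	0.784
SCoT84	acgacatggcgaccacgt	24	21	87.50	0.546	0.370	7.778	12.324	1.000
SCoT87	accatggctaccaccggt	5	5	100.00	0.536	0.357	1.785	2.595	0.378
SCoT90	ccatggctaccaccggca	21	15	71.43	0.561	0.379	5.683	8.378	0.973
SCoT93	accatggctaccagcgca	21	19	90.48	0.541	0.363	6.890	10.054	0.973
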