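feature	rna_class	fc1	p1	fc2	p2	expected1	expected2	expected_pattern
Ccl8	mrna	2.44	0.03	0.25	0.03	up	down	reversed-up
Ssxb5	mrna	0.31	0.00	0.33	0.01	down	down	concordant-down
Cd28	mrna	2.10	0.00	0.59	0.02	up	down	reversed-up
Gm8677	mrna	2.76	0.01	0.36	0.00	up	down	reversed-up
Chil1	mrna	4.73	0.03	0.36	0.02	up	down	reversed-up
Catsper4	mrna	5.35	0.04	0.37	0.02	up	down	reversed-up
Stkld1	mrna	2.61	0.01	0.37	0.02	up	down	reversed-up
Klrk1	mrna	2.15	0.04	0.59	0.02	up	down	reversed-up
Olfr1283	mrna	0.60	0.03	0.38	0.01	down	down	concordant-down
Cdh4	mrna	3.42	0.04	0.41	0.00	up	down	reversed-up
Left1	mrna	2.04	0.03	0.50	0.01	up	down	reversed-up
Cd8a	mrna	3.15	0.01	0.65	0.04	up	down	reversed-up
Cabyr	mrna	0.09	0.00	1.73	0.01	down	up	reversed-down
Cxcl9	mrna	2.09	0.00	0.64	0.15	up	not_de	NA
Il15	mrna	1.62	0.02	0.65	0.02	up	down	reversed-up
Il18r1	mrna	4.44	0.05	0.46	0.05	not_de	not_de	NA
Sbp	mrna	0.34	0.04	2.02	0.05	down	not_de	NA
Rgs9bp	mrna	2.78	0.04	2.12	0.02	up	up	concordant-up
Gadd45b	mrna	9.64	0.04	2.22	0.03	up	up	concordant-up
Zbtb16	mrna	2.69	0.01	2.58	0.02	up	up	concordant-up
Snhg1	lncrna	2.47	0.02	0.63	0.00	up	down	reversed-up
Slc36a3os	lncrna	4.24	0.04	0.35	0.03	up	down	reversed-up
RP24-175C20.19	lncrna	0.61	0.05	1.62	0.01	not_de	up	NA
RP23-62D21.4	lncrna	0.49	0.00	1.98	0.00	down	up	reversed-down
RP23-368K22.5	lncrna	2.31	0.04	0.61	0.05	up	not_de	NA
Rian	lncrna	0.09	0.02	2.47	0.00	down	up	reversed-down
Gm45609	lncrna	0.03	0.00	1.74	0.00	down	up	reversed-down
Gm45414	lncrna	0.43	0.00	1.84	0.01	down	up	reversed-down
Gm45204	lncrna	0.24	0.01	1.97	0.05	down	not_de	NA
Gm44427	lncrna	3.51	0.02	0.65	0.00	up	down	reversed-up
Gm43823	lncrna	0.51	0.03	1.97	0.04	down	up	reversed-down
Gm43814	lncrna	2.39	0.01	0.63	0.05	up	not_de	NA
Gm43168	lncrna	4.24	0.00	0.65	0.04	up	down	reversed-up
Gm43065	lncrna	2.19	0.02	0.55	0.01	up	down	reversed-up
Gm42640	lncrna	1.81	0.02	1.99	0.02	up	up	concordant-up
Gm42599	lncrna	0.46	0.01	2.26	0.05	down	not_de	NA
Gm38351	lncrna	0.43	0.02	1.55	0.02	down	up	reversed-down
Gm37570	lncrna	0.35	0.01	1.91	0.04	down	up	reversed-down
Gm3716	lncrna	1.73	0.04	0.48	0.01	up	down	reversed-up
Gm37143	lncrna	2.92	0.01	0.57	0.01	up	down	reversed-up
Gm28875	lncrna	0.55	0.01	0.66	0.02	down	down	concordant-down
Gm26645	lncrna	2.53	0.05	0.52	0.03	not_de	down	NA
Gm25694	lncrna	0.56	0.02	1.66	0.04	down	up	reversed-down
Gm25545	lncrna	0.26	0.01	2.01	0.02	down	up	reversed-down
Gm20633	lncrna	1.98	0.04	0.28	0.05	up	not_de	NA
Gm20052	lncrna	2.39	0.01	0.60	0.02	up	down	reversed-up
circ_0011264	circrna	0.32	0.01	2.22	0.02	down	up	reversed-down
circ_0010011	circrna	0.24	0.00	1.80	0.03	down	up	reversed-down
circ_0009453	circrna	1.64	0.01	0.53	0.01	up	down	reversed-up
circ_0009212	circrna	2.35	0.04	0.54	0.02	up	down	reversed-up
circ_0009029	circrna	3.56	0.02	0.38	0.02	up	down	reversed-up
circ_0008308	circrna	0.44	0.03	1.76	0.02	down	up	reversed-down
circ_0007662	circrna	0.64	0.01	1.54	0.00	down	up	reversed-down
circ_0007521	circrna	0.35	0.01	1.68	0.03	down	up	reversed-down
circ_0007385	circrna	2.59	0.01	0.45	0.01	up	down	reversed-up
circ_0007379	circrna	0.43	0.03	1.68	0.03	down	up	reversed-down
circ_0004572	circrna	2.69	0.03	0.52	0.05	up	not_de	NA
circ_0003267	circrna	3.11	0.01	1.56	0.04	up	up	concordant-up
circ_0002700	circrna	0.34	0.00	0.66	0.03	down	down	concordant-down
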