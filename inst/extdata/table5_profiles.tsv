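otu_id	effect	isolate	LB-NPK	LB-PK	LB-K	PE-NPK	PE-PK	PE-K	TR-NPK	TR-PK	TR-K	LR-NPK	LR-PK	LR-K
OTU-69	inhibiting	Pantoea sp. RK126	0	0	0	0	0	0	0	0	0	0	0	0
OTU-96	inhibiting	Rhizobacter sp. RK021	0	0	0	0	0	0	0	0	0	0.6	4.4	2.0
OTU-166	inhibiting	Neorhizobium sp. RK064	0	0	0	0	0	0	0	1.2	1.7	2.2	3.7	2.0
OTU-218	inhibiting	Tardiphaga sp. RK140	0	0	0	0	0	0	2.6	1.8	4.5	0.6	0.7	0
OTU-272	inhibiting	Streptomyces sp. TP071	0	0	0	0	0	0	0	0	0	1.7	0.7	0.7
OTU-329	inhibiting	Bacillus sp. TP182	1.7	0	0	2.8	0	0	1.3	0	0.6	0	0	0
OTU-86	promoting	Variovorax sp. RK170	1.1	1.1	4.8	6.2	2.8	1.7	0.7	0.6	0.6	1.7	0	0
OTU-87	promoting	Polaromonas sp. RK103	0	0	0	0	0	0	2.6	1.2	0.6	2.2	1.5	3.3
OTU-170	promoting	Mesorhizobium sp. TP027	0	0	0	0	0	0	0	0	0	0	0	0
OTU-189	promoting	Sphingobium sp. RK166	0	0	0	0	0	0	0.7	0	2.8	0	1.5	2.0
OTU-191	promoting	Sphingomonas sp. RP195	0	0	0	0	0	0	0	0	0	0.6	1.5	1.3
OTU-199	promoting	Sphingopyxis sp. RK106	0	0	0	0	0	0	0	0	0	0	0	0
OTU-226	promoting	Asticcacaulis sp. RK043	0	0	0	0	0	0	0	0	0	0	0.7	0
OTU-301	promoting	Nocardioides sp. RP110	0	0	0	0	0	0	0	0	0	0	0	0
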