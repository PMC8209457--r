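otu_id	isolate	effect	closest_species	identity_pct
OTU-301	Nocardioides sp. RP110	+	Nocardioides cavernae	100
OTU-272	Streptomyces sp. TP071	-	Streptomyces mirabilis	100
OTU-329	Bacillus sp. TP182	-	Bacillus gibsonii	100
OTU-226	Asticcacaulis sp. RK043	+	Asticcacaulis benevestitus	98
OTU-170	Mesorhizobium sp. TP027	+	Mesorhizobium chacoense	98
OTU-166	Neorhizobium sp. RK064	-	Neorhizobium galegae	100
OTU-189	Sphingobium sp. RK166	+	Sphingobium aromaticiconvertens	100
OTU-191	Sphingomonas sp. RP195	+	Sphingomonas asaccharolytica	100
OTU-199	Sphingopyxis sp. RK106	+	Sphingopyxis taejonensis	100
OTU-218	Tardiphaga sp. RK140	-	Tardiphaga robiniae	99
OTU-87	Polaromonas sp. RK103	+	Polaromonas ginsengisoli	100
OTU-86	Variovorax sp. RK170	+	Variovorax paradoxus	100
OTU-69	Pantoea sp. RK126	-	Pantoea ananatis	100
OTU-96	Rhizobacter sp. RK021	-	Methylibium petroleiphilum	99
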