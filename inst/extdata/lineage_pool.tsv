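genus	family	order	class	phylum	pool	species
Methylobacterium	Methylobacteriaceae	Rhizobiales	Alphaproteobacteria	Proteobacteria	neutral
Phyllobacterium	Phyllobacteriaceae	Rhizobiales	Alphaproteobacteria	Proteobacteria	neutral
Rhizobium	Rhizobiaceae	Rhizobiales	Alphaproteobacteria	Proteobacteria	neutral
Mesorhizobium	Phyllobacteriaceae	Rhizobiales	Alphaproteobacteria	Proteobacteria	neutral
Neorhizobium	Rhizobiaceae	Rhizobiales	Alphaproteobacteria	Proteobacteria	neutral
Devosia	Hyphomicrobiaceae	Rhizobiales	Alphaproteobacteria	Proteobacteria	neutral
Tardiphaga	Bradyrhizobiaceae	Rhizobiales	Alphaproteobacteria	Proteobacteria	neutral
Novosphingobium	Sphingomonadaceae	Sphingomonadales	Alphaproteobacteria	Proteobacteria	neutral
Sphingomonas	Sphingomonadaceae	Sphingomonadales	Alphaproteobacteria	Proteobacteria	neutral
Sphingobium	Sphingomonadaceae	Sphingomonadales	Alphaproteobacteria	Proteobacteria	neutral
Sphingopyxis	Sphingomonadaceae	Sphingomonadales	Alphaproteobacteria	Proteobacteria	neutral
Asticcacaulis	Caulobacteraceae	Caulobacterales	Alphaproteobacteria	Proteobacteria	neutral
Polaromonas	Comamonadaceae	Burkholderiales	Betaproteobacteria	Proteobacteria	neutral
Rhizobacter	Pseudomonadaceae	Pseudomonadales	Gammaproteobacteria	Proteobacteria	neutral
Niastella	Chitinophagaceae	Sphingobacteriales	Sphingobacteriia	Bacteroidetes	neutral
Streptomyces	Streptomycetaceae	Actinomycetales	Actinobacteria	Actinobacteria	neutral
Nocardioides	Nocardioidaceae	Actinomycetales	Actinobacteria	Actinobacteria	neutral
Microbacterium	Microbacteriaceae	Actinomycetales	Actinobacteria	Actinobacteria	neutral
Arthrobacter	Micrococcaceae	Actinomycetales	Actinobacteria	Actinobacteria	neutral
Mycobacterium	Mycobacteriaceae	Actinomycetales	Actinobacteria	Actinobacteria	neutral
Curtobacterium	Microbacteriaceae	Actinomycetales	Actinobacteria	Actinobacteria	neutral
Pseudomonas	Pseudomonadaceae	Pseudomonadales	Gammaproteobacteria	Proteobacteria	pgpb
Bacillus	Bacillaceae	Bacillales	Bacilli	Firmicutes	pgpb
Paenibacillus	Paenibacillaceae	Bacillales	Bacilli	Firmicutes	pgpb
Stenotrophomonas	Xanthomonadaceae	Xanthomonadales	Gammaproteobacteria	Proteobacteria	pgpb
Chryseobacterium	Flavobacteriaceae	Flavobacteriales	Flavobacteriia	Bacteroidetes	pgpb
Rhodobacter	Rhodobacteraceae	Rhodobacterales	Alphaproteobacteria	Proteobacteria	pgpb
Variovorax	Comamonadaceae	Burkholderiales	Betaproteobacteria	Proteobacteria	pgpb
Acinetobacter	Moraxellaceae	Pseudomonadales	Gammaproteobacteria	Proteobacteria	pgpb
Pantoea	Enterobacteriaceae	Enterobacteriales	Gammaproteobacteria	Proteobacteria	pathogen	Pantoea ananatis
Ralstonia	Burkholderiaceae	Burkholderiales	Betaproteobacteria	Proteobacteria	pathogen	Ralstonia solanacearum
Xanthomonas	Xanthomonadaceae	Xanthomonadales	Gammaproteobacteria	Proteobacteria	pathogen	Xanthomonas campestris
Agrobacterium	Rhizobiaceae	Rhizobiales	Alphaproteobacteria	Proteobacteria	pathogen	Agrobacterium tumefaciens
Clavibacter	Microbacteriaceae	Actinomycetales	Actinobacteria	Actinobacteria	pathogen	Clavibacter michiganensis
Pectobacterium	Enterobacteriaceae	Enterobacteriales	Gammaproteobacteria	Proteobacteria	pathogen	Pectobacterium carotovorum
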