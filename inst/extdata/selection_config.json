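{
  "novelty_threshold": 0.97,
  "abundance_threshold": 0.01,
  "target_tissues": ["taproot", "lateral_root"],
  "known_pgpb_genera": ["Acinetobacter", "Bacillus", "Burkholderia",
    "Chryseobacterium", "Pseudomonas", "Paenibacillus", "Rhodobacter",
    "Stenotrophomonas", "Variovorax"],
  "pathogen_taxa": ["Pantoea ananatis", "Ralstonia solanacearum",
    "Pseudomonas syringae", "Xanthomonas campestris", "Erwinia amylovora",
    "Clavibacter michiganensis", "Pectobacterium carotovorum",
    "Agrobacterium tumefaciens", "Dickeya dadantii",
    "Staphylococcus aureus", "Klebsiella pneumoniae"],
  "pathogen_match": "species"
}
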