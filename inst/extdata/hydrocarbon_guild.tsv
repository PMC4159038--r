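# Default hydrocarbon-biodegradation guild, version 1.0.0
# 63 bacterial genera with at least one described hydrocarbon-degrading strain.
# RECONSTRUCTED list: the original supplementary catalogue is not bundled, so
# this file combines the genera named in the defining study's main text with
# canonical hydrocarbon-degrading genera from the primary literature,
# constrained to the published composition: 63 genera, 45 Proteobacteria
# (71.4%), 12 Actinobacteria (19.0%), 3 Bacteroidetes (4.8%), 3 Firmicutes
# (4.8%). It is a replaceable data asset: edit or supply your own TSV with the
# same columns. Psychromonas is deliberately absent (no described
# hydrocarbon-degrading strain at the time of definition).
# Columns: genus, phylum, isolation_environment {marine|terrestrial|both|unknown},
# synonyms (semicolon-separated), evidence_note.
genus	phylum	isolation_environment	synonyms	evidence_note
Alcanivorax	Proteobacteria	marine		obligate hydrocarbonoclastic; alkane degradation
Cycloclasticus	Proteobacteria	marine		obligate hydrocarbonoclastic; PAH degradation
Oleispira	Proteobacteria	marine		psychrophilic obligate hydrocarbonoclastic; alkanes
Oleiphilus	Proteobacteria	marine		obligate hydrocarbonoclastic; alkanes
Thalassolituus	Proteobacteria	marine		obligate hydrocarbonoclastic; alkanes
Oleibacter	Proteobacteria	marine		alkane degradation in tropical seawater
Marinobacter	Proteobacteria	marine		aliphatic and aromatic hydrocarbon degradation
Marinobacterium	Proteobacteria	marine		crude-oil degrading isolates
Neptunomonas	Proteobacteria	marine		naphthalene degradation
Pseudoalteromonas	Proteobacteria	marine		PAH degradation in cold seawater
Alteromonas	Proteobacteria	marine		PAH degradation
Glaciecola	Proteobacteria	marine		enriched in cold-water oil amendments
Colwellia	Proteobacteria	marine		hydrocarbon degradation in deep cold waters
Shewanella	Proteobacteria	both		PAH degradation
Halomonas	Proteobacteria	both		aromatic degradation in saline systems
Vibrio	Proteobacteria	marine		PAH-degrading strains
Photobacterium	Proteobacteria	marine		phenanthrene-degrading strains
Roseobacter	Proteobacteria	marine		aromatic compound degradation (Roseobacter clade)
Roseovarius	Proteobacteria	marine		oil-degrading members of the Roseobacter clade
Jannaschia	Proteobacteria	marine		Roseobacter clade; oil-associated enrichment
Sulfitobacter	Proteobacteria	both		Roseobacter clade; aromatic degradation
Paracoccus	Proteobacteria	both		PAH degradation
Thalassospira	Proteobacteria	marine		PAH degradation in oligotrophic seawater
Sphingopyxis	Proteobacteria	both		aromatic hydrocarbon degradation
Sphingomonas	Proteobacteria	terrestrial		versatile aromatic and PAH degradation
Sphingobium	Proteobacteria	terrestrial		PAH and chlorinated aromatic degradation
Novosphingobium	Proteobacteria	both		PAH degradation
Brevundimonas	Proteobacteria	both		petroleum-degrading isolates
Acinetobacter	Proteobacteria	terrestrial		alkane degradation (alkM)
Pseudomonas	Proteobacteria	both		model alkane and aromatic degraders (alk, nah, xyl)
Stenotrophomonas	Proteobacteria	terrestrial		PAH-degrading strains
Burkholderia	Proteobacteria	terrestrial		aromatic and PAH degradation
Ralstonia	Proteobacteria	terrestrial		aromatic compound degradation
Cupriavidus	Proteobacteria	terrestrial		aromatic compound degradation
Comamonas	Proteobacteria	terrestrial		phenanthrene degradation
Delftia	Proteobacteria	terrestrial		aromatic degradation
Acidovorax	Proteobacteria	terrestrial		PAH degradation
Hydrogenophaga	Proteobacteria	terrestrial		benzene and PAH degradation
Polaromonas	Proteobacteria	terrestrial		naphthalene degradation in cold soils
Achromobacter	Proteobacteria	terrestrial		petroleum hydrocarbon degradation
Alcaligenes	Proteobacteria	terrestrial		aromatic hydrocarbon degradation
Azoarcus	Proteobacteria	terrestrial		anaerobic toluene degradation
Thauera	Proteobacteria	terrestrial		anaerobic aromatic degradation
Geobacter	Proteobacteria	both		anaerobic toluene and benzene degradation
Desulfobacula	Proteobacteria	marine		anaerobic toluene degradation (sulfate reducer)
Rhodococcus	Actinobacteria	both		broad alkane and aromatic degradation
Mycobacterium	Actinobacteria	both		high-molecular-weight PAH degradation
Nocardia	Actinobacteria	terrestrial		alkane and aromatic degradation
Nocardioides	Actinobacteria	both		PAH degradation
Gordonia	Actinobacteria	both		alkane and branched-alkane degradation
Dietzia	Actinobacteria	both		long-chain alkane degradation
Corynebacterium	Actinobacteria	terrestrial		petroleum-degrading strains
Arthrobacter	Actinobacteria	terrestrial		PAH and phenol degradation
Microbacterium	Actinobacteria	both		PAH-degrading strains
Micrococcus	Actinobacteria	terrestrial		crude-oil degrading strains
Streptomyces	Actinobacteria	terrestrial		hydrocarbon-degrading strains
Janibacter	Actinobacteria	both		dibenzofuran and PAH degradation
Flavobacterium	Bacteroidetes	both		petroleum hydrocarbon degradation
Chryseobacterium	Bacteroidetes	terrestrial		diesel-range hydrocarbon degradation
Sphingobacterium	Bacteroidetes	terrestrial		crude-oil degrading strains
Bacillus	Firmicutes	both		alkane and PAH-degrading strains
Geobacillus	Firmicutes	terrestrial		thermophilic long-chain alkane degradation
Planococcus	Firmicutes	marine		alkane-degrading strains
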