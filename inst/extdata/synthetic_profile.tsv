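#SampleID	clade_abundance
k__Bacteria	100.0
k__Bacteria|p__Firmicutes	58.3
k__Bacteria|p__Bacteroidetes	39.2
k__Bacteria|p__Proteobacteria	2.5
k__Bacteria|p__Firmicutes|c__Clostridia	45.1
k__Bacteria|p__Firmicutes|c__Bacilli	13.2
k__Bacteria|p__Bacteroidetes|c__Bacteroidia	39.2
k__Bacteria|p__Proteobacteria|c__Gammaproteobacteria	2.5
k__Bacteria|p__Firmicutes|c__Clostridia|o__Clostridiales	45.1
k__Bacteria|p__Firmicutes|c__Clostridia|o__Clostridiales|f__Lachnospiraceae	28.4
k__Bacteria|p__Firmicutes|c__Clostridia|o__Clostridiales|f__Ruminococcaceae	16.7
k__Bacteria|p__Firmicutes|c__Clostridia|o__Clostridiales|f__Lachnospiraceae|g__Blautia	15.1
k__Bacteria|p__Firmicutes|c__Clostridia|o__Clostridiales|f__Lachnospiraceae|g__Roseburia	13.3
k__Bacteria|p__Firmicutes|c__Clostridia|o__Clostridiales|f__Ruminococcaceae|g__Faecalibacterium	16.7
k__Bacteria|p__Firmicutes|c__Clostridia|o__Clostridiales|f__Ruminococcaceae|g__Faecalibacterium|s__Faecalibacterium_prausnitzii	16.7
k__Bacteria|p__Firmicutes|c__Clostridia|o__Clostridiales|f__Lachnospiraceae|g__Blautia|s__Blautia_obeum	15.1
k__Bacteria|p__Firmicutes|c__Clostridia|o__Clostridiales|f__Lachnospiraceae|g__Roseburia|s__Roseburia_intestinalis	13.3
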