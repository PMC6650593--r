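function	taxon_selector
nitrate_reduction	Comamonadaceae
nitrate_reduction	Rhodobacter
aerobic_ammonia_oxidation	Nitrosomonadaceae
fermentation	Saprospiraceae
fermentation	Cytophagaceae
hydrocarbon_degradation	Acetobacteraceae
ureolysis	Herbaspirillum
human_pathogens	Flavobacterium
photoautotrophy	Cyanobacteria
chitinolysis	Flectobacillus
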