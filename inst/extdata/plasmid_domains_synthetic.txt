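# Synthetic placeholder marker-domain list for plasmid classification.
# The classification rule takes any user-supplied list of plasmid-specific
# domain accessions; this small stand-in exists for examples and tests
# only and is NOT the curated list used in production analyses.
PF01051
PF01446
PF01719
PF02387
PF02486
PF03090
PF03432
PF04796
PF05732
PF06970
PF07506
PF08998
PF09140
PF10609
PF11740
PF12684
PF13362
PF13588
PF14659
PF16793
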