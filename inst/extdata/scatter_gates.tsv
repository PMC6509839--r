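preferred_label	basis	spelling
lymphocyte	size_fsc_ssc	lymphocyte
lymphocyte	size_fsc_ssc	ly
lymphocyte	size_fsc_ssc	lymp
lymphocyte	size_fsc_ssc	lymph
lymphocyte	size_fsc_ssc	Lymph
lymphocyte	size_fsc_ssc	Lymphs
lymphocyte	size_fsc_ssc	Lymp
lymphocyte	size_fsc_ssc	Lymphocytes
monocyte	size_fsc_ssc	monocyte
monocyte	size_fsc_ssc	mo
monocyte	size_fsc_ssc	mono
monocyte	size_fsc_ssc	monos
monocyte	size_fsc_ssc	MNC
monocyte	size_fsc_ssc	Monocytes
monocyte	size_fsc_ssc	Mono
granulocyte	size_fsc_ssc	granulocyte
granulocyte	size_fsc_ssc	Gran
intact	size_fsc_ssc	intact
intact	size_fsc_ssc	Intact_cells
intact	size_fsc_ssc	Intact_cells_population
singlet	relative_dimensions	singlet
singlet	relative_dimensions	sing
singlet	relative_dimensions	singlets
singlet	relative_dimensions	Singlet
singlet	relative_dimensions	Singlets
singlet	relative_dimensions	doublet_excluded
singlet	relative_dimensions	sing-F
singlet	relative_dimensions	intact_singlet
viable	dye	viable
viable	dye	live
viable	dye	Annexin-
viable	dye	live/dead stain-?
proliferated	dye	proliferated
proliferated	dye	CFSE-
proliferated	dye	TracerViolet-
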