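id	preferred_label	tier	synonym	marker_class
PR:900000001	BDCA-2	short_label	BDCA-2	protein
PR:900000001	BDCA-2	manual	BDCA2	protein
PR:900000002	KLRB1	short_label	KLRB1	protein
PR:900000002	KLRB1	manual	CD161	protein
PR:900000003	MKI67	short_label	MKI67	protein
PR:900000003	MKI67	exact_synonym	KI-67	protein
PR:900000003	MKI67	manual	KI67	protein
PR:900000004	PDCD1	short_label	PDCD1	protein
PR:900000004	PDCD1	exact_synonym	CD279	protein
PR:900000004	PDCD1	manual	PD1	protein
PR:900000005	TNF-a	short_label	TNF-a	protein
PR:900000005	TNF-a	manual	TNFa	protein
PR:000025402	CD8	exact_synonym	CD8 protein complex	protein_complex
PR:000025402	CD8	manual	CD8	protein_complex
PR:000001020	CD3e	short_label	CD3E	protein
PR:000001020	CD3e	exact_synonym	T-cell surface glycoprotein CD3 epsilon chain	protein
PR:000001020	CD3e	manual	CD3	protein
PR:000036952	HLA-DRB	short_label	HLA-DRB	protein
PR:000036952	HLA-DRB	manual	HLA-DR	protein
PR:000036952	HLA-DRB	manual	HLADR	protein
PR:000003075	pSTAT1	exact_synonym	phosphorylated STAT1	phospho_protein
PR:000003075	pSTAT1	manual	pSTAT1	phospho_protein
PR:900000010	pSTAT3	exact_synonym	phosphorylated STAT3	phospho_protein
PR:900000010	pSTAT3	manual	pSTAT3	phospho_protein
PR:900000011	pSTAT5	exact_synonym	phosphorylated STAT5	phospho_protein
PR:900000011	pSTAT5	manual	pSTAT5	phospho_protein
PR:900000012	LIN	manual	LIN	disallowed
PR:900000012	LIN	manual	lineage	disallowed
PR:900000013	CD4	short_label	CD4	protein
PR:900000013	CD4	exact_synonym	CD4 molecule	protein
PR:900000013	CD4	exact_synonym	T-cell surface glycoprotein CD4	protein
PR:900000014	CD14	short_label	CD14	protein
PR:900000014	CD14	exact_synonym	monocyte differentiation antigen CD14	protein
PR:900000015	CD19	short_label	CD19	protein
PR:900000015	CD19	exact_synonym	B-lymphocyte antigen CD19	protein
PR:900000016	CD20	short_label	CD20	protein
PR:900000016	CD20	exact_synonym	B-lymphocyte antigen CD20	protein
PR:900000017	CD27	short_label	CD27	protein
PR:900000017	CD27	exact_synonym	CD27 antigen	protein
PR:900000018	CD38	short_label	CD38	protein
PR:900000018	CD38	exact_synonym	ADP-ribosyl cyclase 1	protein
PR:900000019	CD45RA	short_label	CD45RA	protein
PR:900000019	CD45RA	exact_synonym	receptor-type tyrosine-protein phosphatase C isoform CD45RA	protein
PR:900000020	CCR7	short_label	CCR7	protein
PR:900000020	CCR7	exact_synonym	C-C chemokine receptor type 7	protein
PR:900000020	CCR7	manual	CD197	protein
PR:900000021	IL2RA	short_label	IL2RA	protein
PR:900000021	IL2RA	exact_synonym	interleukin-2 receptor subunit alpha	protein
PR:900000021	IL2RA	exact_synonym	CD25	protein
PR:900000022	BDCA-3	short_label	BDCA-3	protein
PR:900000022	BDCA-3	manual	BDCA3	protein
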