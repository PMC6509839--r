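cl_id	label	parent_id	definition
CL:0000236	B cell		
CL:0000784	plasmacytoid dendritic cell		
CL:0000789	alpha-beta T cell		
CL:0000624	CD4-positive, alpha-beta T cell	CL:0000789	alpha-beta T cell and has_plasma_membrane_part some CD4 molecule
CL:0000897	CD4-positive, alpha-beta memory T cell	CL:0000624	CD4-positive, alpha-beta T cell
CL:0000905	effector memory CD4-positive, alpha-beta T cell	CL:0000897	CD4-positive, alpha-beta memory T cell and lacks_plasma_membrane_part some receptor-type tyrosine-protein phosphatase C isoform CD45RA and lacks_plasma_membrane_part some C-C chemokine receptor type 7 and lacks_plasma_membrane_part some interleukin-2 receptor subunit alpha
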