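B_cells	synthetic marker set	B_cells_M1	B_cells_M2	B_cells_M3	B_cells_M4	B_cells_M5	B_cells_M6	B_cells_M7	B_cells_M8
CD8_T_cells	synthetic marker set	CD8_T_cells_M1	CD8_T_cells_M2	CD8_T_cells_M3	CD8_T_cells_M4	CD8_T_cells_M5	CD8_T_cells_M6	CD8_T_cells_M7	CD8_T_cells_M8
T_helper_cells	synthetic marker set	T_helper_cells_M1	T_helper_cells_M2	T_helper_cells_M3	T_helper_cells_M4	T_helper_cells_M5	T_helper_cells_M6	T_helper_cells_M7	T_helper_cells_M8
Th17_cells	synthetic marker set	Th17_cells_M1	Th17_cells_M2	Th17_cells_M3	Th17_cells_M4	Th17_cells_M5	Th17_cells_M6	Th17_cells_M7	Th17_cells_M8
NK_CD56bright_cells	synthetic marker set	NK_CD56bright_cells_M1	NK_CD56bright_cells_M2	NK_CD56bright_cells_M3	NK_CD56bright_cells_M4	NK_CD56bright_cells_M5	NK_CD56bright_cells_M6	NK_CD56bright_cells_M7	NK_CD56bright_cells_M8
NK_CD56dim_cells	synthetic marker set	NK_CD56dim_cells_M1	NK_CD56dim_cells_M2	NK_CD56dim_cells_M3	NK_CD56dim_cells_M4	NK_CD56dim_cells_M5	NK_CD56dim_cells_M6	NK_CD56dim_cells_M7	NK_CD56dim_cells_M8
T_cells	synthetic marker set	T_cells_M1	T_cells_M2	T_cells_M3	T_cells_M4	T_cells_M5	T_cells_M6	T_cells_M7	T_cells_M8
Th1_cells	synthetic marker set	Th1_cells_M1	Th1_cells_M2	Th1_cells_M3	Th1_cells_M4	Th1_cells_M5	Th1_cells_M6	Th1_cells_M7	Th1_cells_M8
Th2_cells	synthetic marker set	Th2_cells_M1	Th2_cells_M2	Th2_cells_M3	Th2_cells_M4	Th2_cells_M5	Th2_cells_M6	Th2_cells_M7	Th2_cells_M8
Tcm	synthetic marker set	Tcm_M1	Tcm_M2	Tcm_M3	Tcm_M4	Tcm_M5	Tcm_M6	Tcm_M7	Tcm_M8
Tem	synthetic marker set	Tem_M1	Tem_M2	Tem_M3	Tem_M4	Tem_M5	Tem_M6	Tem_M7	Tem_M8
TFH	synthetic marker set	TFH_M1	TFH_M2	TFH_M3	TFH_M4	TFH_M5	TFH_M6	TFH_M7	TFH_M8
Tgd	synthetic marker set	Tgd_M1	Tgd_M2	Tgd_M3	Tgd_M4	Tgd_M5	Tgd_M6	Tgd_M7	Tgd_M8
Treg	synthetic marker set	Treg_M1	Treg_M2	Treg_M3	Treg_M4	Treg_M5	Treg_M6	Treg_M7	Treg_M8
NK_cells	synthetic marker set	NK_cells_M1	NK_cells_M2	NK_cells_M3	NK_cells_M4	NK_cells_M5	NK_cells_M6	NK_cells_M7	NK_cells_M8
Cytotoxic_cells	synthetic marker set	Cytotoxic_cells_M1	Cytotoxic_cells_M2	Cytotoxic_cells_M3	Cytotoxic_cells_M4	Cytotoxic_cells_M5	Cytotoxic_cells_M6	Cytotoxic_cells_M7	Cytotoxic_cells_M8
DC	synthetic marker set	DC_M1	DC_M2	DC_M3	DC_M4	DC_M5	DC_M6	DC_M7	DC_M8
aDC	synthetic marker set	aDC_M1	aDC_M2	aDC_M3	aDC_M4	aDC_M5	aDC_M6	aDC_M7	aDC_M8
iDC	synthetic marker set	iDC_M1	iDC_M2	iDC_M3	iDC_M4	iDC_M5	iDC_M6	iDC_M7	iDC_M8
pDC	synthetic marker set	pDC_M1	pDC_M2	pDC_M3	pDC_M4	pDC_M5	pDC_M6	pDC_M7	pDC_M8
Macrophages	synthetic marker set	Macrophages_M1	Macrophages_M2	Macrophages_M3	Macrophages_M4	Macrophages_M5	Macrophages_M6	Macrophages_M7	Macrophages_M8
Mast_cells	synthetic marker set	Mast_cells_M1	Mast_cells_M2	Mast_cells_M3	Mast_cells_M4	Mast_cells_M5	Mast_cells_M6	Mast_cells_M7	Mast_cells_M8
Neutrophils	synthetic marker set	Neutrophils_M1	Neutrophils_M2	Neutrophils_M3	Neutrophils_M4	Neutrophils_M5	Neutrophils_M6	Neutrophils_M7	Neutrophils_M8
Eosinophils	synthetic marker set	Eosinophils_M1	Eosinophils_M2	Eosinophils_M3	Eosinophils_M4	Eosinophils_M5	Eosinophils_M6	Eosinophils_M7	Eosinophils_M8
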