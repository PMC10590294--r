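sig_Bcell	placeholder synthetic panel	Bcell_g01	Bcell_g02	Bcell_g03	Bcell_g04	Bcell_g05	Bcell_g06	Bcell_g07	Bcell_g08	Bcell_g09	Bcell_g10
sig_CD4Tcell	placeholder synthetic panel	CD4Tcell_g01	CD4Tcell_g02	CD4Tcell_g03	CD4Tcell_g04	CD4Tcell_g05	CD4Tcell_g06	CD4Tcell_g07	CD4Tcell_g08	CD4Tcell_g09	CD4Tcell_g10
sig_CD8Tcell	placeholder synthetic panel	CD8Tcell_g01	CD8Tcell_g02	CD8Tcell_g03	CD8Tcell_g04	CD8Tcell_g05	CD8Tcell_g06	CD8Tcell_g07	CD8Tcell_g08	CD8Tcell_g09	CD8Tcell_g10
sig_NKcell	placeholder synthetic panel	NKcell_g01	NKcell_g02	NKcell_g03	NKcell_g04	NKcell_g05	NKcell_g06	NKcell_g07	NKcell_g08	NKcell_g09	NKcell_g10
sig_Monocyte	placeholder synthetic panel	Monocyte_g01	Monocyte_g02	Monocyte_g03	Monocyte_g04	Monocyte_g05	Monocyte_g06	Monocyte_g07	Monocyte_g08	Monocyte_g09	Monocyte_g10
sig_Macrophage	placeholder synthetic panel	Macrophage_g01	Macrophage_g02	Macrophage_g03	Macrophage_g04	Macrophage_g05	Macrophage_g06	Macrophage_g07	Macrophage_g08	Macrophage_g09	Macrophage_g10
sig_Dendritic	placeholder synthetic panel	Dendritic_g01	Dendritic_g02	Dendritic_g03	Dendritic_g04	Dendritic_g05	Dendritic_g06	Dendritic_g07	Dendritic_g08	Dendritic_g09	Dendritic_g10
sig_Treg	placeholder synthetic panel	Treg_g01	Treg_g02	Treg_g03	Treg_g04	Treg_g05	Treg_g06	Treg_g07	Treg_g08	Treg_g09	Treg_g10
sig_Texhausted	placeholder synthetic panel	Texhausted_g01	Texhausted_g02	Texhausted_g03	Texhausted_g04	Texhausted_g05	Texhausted_g06	Texhausted_g07	Texhausted_g08	Texhausted_g09	Texhausted_g10
sig_Tnaive	placeholder synthetic panel	Tnaive_g01	Tnaive_g02	Tnaive_g03	Tnaive_g04	Tnaive_g05	Tnaive_g06	Tnaive_g07	Tnaive_g08	Tnaive_g09	Tnaive_g10
sig_Tmemory	placeholder synthetic panel	Tmemory_g01	Tmemory_g02	Tmemory_g03	Tmemory_g04	Tmemory_g05	Tmemory_g06	Tmemory_g07	Tmemory_g08	Tmemory_g09	Tmemory_g10
sig_Teffector	placeholder synthetic panel	Teffector_g01	Teffector_g02	Teffector_g03	Teffector_g04	Teffector_g05	Teffector_g06	Teffector_g07	Teffector_g08	Teffector_g09	Teffector_g10
sig_Tcytotoxic	placeholder synthetic panel	Tcytotoxic_g01	Tcytotoxic_g02	Tcytotoxic_g03	Tcytotoxic_g04	Tcytotoxic_g05	Tcytotoxic_g06	Tcytotoxic_g07	Tcytotoxic_g08	Tcytotoxic_g09	Tcytotoxic_g10
gene_IMM01	placeholder synthetic panel	IMM01
gene_IMM02	placeholder synthetic panel	IMM02
gene_IMM03	placeholder synthetic panel	IMM03
gene_IMM04	placeholder synthetic panel	IMM04
gene_IMM05	placeholder synthetic panel	IMM05
gene_IMM06	placeholder synthetic panel	IMM06
gene_IMM07	placeholder synthetic panel	IMM07
gene_IMM08	placeholder synthetic panel	IMM08
gene_IMM09	placeholder synthetic panel	IMM09
gene_IMM10	placeholder synthetic panel	IMM10
gene_IMM11	placeholder synthetic panel	IMM11
gene_IMM12	placeholder synthetic panel	IMM12
gene_IMM13	placeholder synthetic panel	IMM13
gene_IMM14	placeholder synthetic panel	IMM14
gene_IMM15	placeholder synthetic panel	IMM15
gene_IMM16	placeholder synthetic panel	IMM16
gene_IMM17	placeholder synthetic panel	IMM17
gene_IMM18	placeholder synthetic panel	IMM18
gene_IMM19	placeholder synthetic panel	IMM19
gene_IMM20	placeholder synthetic panel	IMM20
gene_IMM21	placeholder synthetic panel	IMM21
gene_IMM22	placeholder synthetic panel	IMM22
gene_IMM23	placeholder synthetic panel	IMM23
gene_IMM24	placeholder synthetic panel	IMM24
gene_IMM25	placeholder synthetic panel	IMM25
gene_IMM26	placeholder synthetic panel	IMM26
gene_IMM27	placeholder synthetic panel	IMM27
gene_IMM28	placeholder synthetic panel	IMM28
gene_IMM29	placeholder synthetic panel	IMM29
gene_IMM30	placeholder synthetic panel	IMM30
gene_IMM31	placeholder synthetic panel	IMM31
gene_IMM32	placeholder synthetic panel	IMM32
gene_IMM33	placeholder synthetic panel	IMM33
gene_IMM34	placeholder synthetic panel	IMM34
gene_IMM35	placeholder synthetic panel	IMM35
gene_IMM36	placeholder synthetic panel	IMM36
gene_IMM37	placeholder synthetic panel	IMM37
gene_IMM38	placeholder synthetic panel	IMM38
gene_IMM39	placeholder synthetic panel	IMM39
gene_IMM40	placeholder synthetic panel	IMM40
gene_IMM41	placeholder synthetic panel	IMM41
gene_IMM42	placeholder synthetic panel	IMM42
gene_IMM43	placeholder synthetic panel	IMM43
gene_IMM44	placeholder synthetic panel	IMM44
gene_IMM45	placeholder synthetic panel	IMM45
gene_IMM46	placeholder synthetic panel	IMM46
gene_IMM47	placeholder synthetic panel	IMM47
gene_IMM48	placeholder synthetic panel	IMM48
gene_IMM49	placeholder synthetic panel	IMM49
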